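# Fiber-model B-DNA construction: straight duplexes and superhelically bent
# (nucleosome-like) duplexes, built from idealized cylindrical coordinates.
#
# The model is schematic: each residue carries only the analysis-relevant
# atoms (backbone P/O1P/O2P, the glycosidic nitrogen, the purine N1 used as
# base-pair center, and the minor/major groove reference atoms). Atom
# positions are placed on a cylinder of canonical B-DNA dimensions; the
# placement angles put minor-edge atoms in the minor-groove gap between the
# backbones and major-edge atoms on the opposite side.

BDNA_RISE <- 3.38     # A per bp step
BDNA_TWIST <- 36      # degrees per bp step
BDNA_P_RADIUS <- 9.0  # A, backbone P radial distance from helix axis
BDNA_PHI0 <- 50       # degrees, backbone azimuthal half-gap across the minor groove

# (atom_name, radius A, azimuth offset deg, axial offset A) per base type.
# The azimuth offset is multiplied by the strand sense so that paired bases
# present their minor edges toward the same groove.
base_atom_spec <- function(base) {
  pur <- rbind(
    c("N9", 5.9, 55, 0), c("N1", 2.0, 95, 0), c("N3", 3.0, 10, 0),
    c("C5", 3.5, 185, 0), c("C6", 2.8, 160, 0), c("N7", 4.0, 200, 0),
    c("C8", 4.4, 215, 0)
  )
  spec <- switch(base,
    A = pur,
    G = rbind(pur, c("N2", 3.3, 20, 0), c("O6", 2.9, 150, 0)),
    C = rbind(c("N1", 5.9, 55, 0), c("O2", 3.2, 15, 0), c("N4", 2.9, 150, 0),
              c("C5", 3.5, 175, 0), c("C6", 4.2, 190, 0)),
    T = rbind(c("N1", 5.9, 55, 0), c("O2", 3.2, 15, 0),
              c("C5", 3.5, 175, 0), c("C6", 4.2, 190, 0))
  )
  data.frame(name = spec[, 1L], rho = as.numeric(spec[, 2L]),
             dphi = as.numeric(spec[, 3L]), dz = as.numeric(spec[, 4L]),
             stringsAsFactors = FALSE)
}

validate_sequence <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop_dnacage("invalid base '%s' at position %d of sequence",
                 chars[bad[1L]], bad[1L])
  chars
}

# Axis frames for a straight duplex: origin on the z axis, local axes = lab axes.
straight_frames <- function(n, rise) {
  lapply(seq_len(n), function(i) {
    list(origin = c(0, 0, (i - 1) * rise),
         ex = c(1, 0, 0), ey = c(0, 1, 0), ez = c(0, 0, 1))
  })
}

# Axis frames along a superhelical path of given radius and pitch,
# parameterized by contour length (one bp per `rise` of contour).
superhelix_frames <- function(n, rise, radius, pitch) {
  cc <- pitch / (2 * pi)
  L <- sqrt(radius^2 + cc^2)
  lapply(seq_len(n), function(i) {
    s <- (i - 1) * rise
    t <- s / L
    origin <- c(radius * cos(t), radius * sin(t), cc * t)
    ez <- c(-radius * sin(t), radius * cos(t), cc) / L    # tangent
    ex <- c(-cos(t), -sin(t), 0)                          # toward superhelix axis
    ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
            ez[3] * ex[1] - ez[1] * ex[3],
            ez[1] * ex[2] - ez[2] * ex[1])
    list(origin = origin, ex = ex, ey = ey, ez = ez)
  })
}

# Place all atoms of a duplex given per-bp axis frames and per-bp backbone
# half-gap angles phi0 (degrees). Returns a molsys with one duplex.
fiber_duplex <- function(sequence, rise = BDNA_RISE, twist = BDNA_TWIST,
                         phi0 = BDNA_PHI0, frames = NULL,
                         chain_ids = c("A", "B"), phase = 0) {
  chars <- validate_sequence(sequence)
  n <- length(chars)
  if (is.null(frames)) frames <- straight_frames(n, rise)
  phi0 <- rep_len(phi0, n)
  theta <- phase + (seq_len(n) - 1) * twist
  rows <- list(); k <- 0L
  place <- function(frame, rho, phi_deg, dz) {
    a <- phi_deg * pi / 180
    frame$origin + rho * cos(a) * frame$ex + rho * sin(a) * frame$ey +
      dz * frame$ez
  }
  add_residue <- function(chain, resno, resname, bp_i, sense, base) {
    fr <- frames[[bp_i]]
    out <- list()
    if ((sense > 0 && bp_i > 1L) || (sense < 0 && bp_i < n)) {
      # phosphate linking to the 5' neighbour along this strand
      zoff <- -sense * rise / 2
      out[["P"]] <- place(fr, BDNA_P_RADIUS,
                          theta[bp_i] + sense * phi0[bp_i], zoff)
      out[["O1P"]] <- place(fr, 9.6, theta[bp_i] + sense * (phi0[bp_i] + 8),
                            zoff + 0.85)
      out[["O2P"]] <- place(fr, 9.6, theta[bp_i] + sense * (phi0[bp_i] - 8),
                            zoff - 0.85)
    }
    spec <- base_atom_spec(base)
    for (r in seq_len(nrow(spec)))
      out[[spec$name[r]]] <- place(fr, spec$rho[r],
                                   theta[bp_i] + sense * spec$dphi[r],
                                   spec$dz[r])
    for (nm in names(out)) {
      k <<- k + 1L
      rows[[k]] <<- list(atom_name = nm, residue_name = resname,
                         residue_index = resno, chain_id = chain,
                         xyz = out[[nm]])
    }
  }
  for (b in seq_len(n))
    add_residue(chain_ids[1L], b, paste0("D", chars[b]), b, +1, chars[b])
  for (m in seq_len(n)) {
    b <- n + 1L - m
    base <- complement_base(chars[b])
    add_residue(chain_ids[2L], m, paste0("D", base), b, -1, base)
  }
  atoms <- atom_table(
    atom_id = seq_len(k),
    atom_name = vapply(rows, `[[`, character(1L), "atom_name"),
    residue_name = vapply(rows, `[[`, character(1L), "residue_name"),
    residue_index = vapply(rows, function(r) r$residue_index, numeric(1L)),
    chain_id = vapply(rows, `[[`, character(1L), "chain_id"),
    xyz = t(vapply(rows, `[[`, numeric(3L), "xyz"))
  )
  dup <- duplex_from_atoms(atoms, chain_ids[1L], chain_ids[2L])
  molecular_system(atoms, duplexes = list(dup))
}

#' Build an idealized straight B-DNA duplex
#'
#' Fiber-model duplex: base pairs stacked along a straight axis with constant
#' helical rise and twist. Every residue carries the backbone P/O1P/O2P
#' atoms (absent on the 5'-terminal residue of each strand), the glycosidic
#' nitrogen, the purine N1 used as base-pair center, and the minor/major
#' groove reference atoms.
#'
#' @param sequence strand-I sequence, 5' to 3', over A/C/G/T.
#' @param rise helical rise per base-pair step, Angstrom (default 3.38).
#' @param twist helical twist per step, degrees (default 36).
#' @param chain_ids two chain identifiers for the strands.
#' @param phase initial azimuth of the first base pair, degrees.
#' @return a `"molsys"` holding one duplex and its atoms.
#' @examples
#' sys <- build_bdna("CGCGAATTCGCG")
#' sys
#' @export
build_bdna <- function(sequence, rise = BDNA_RISE, twist = BDNA_TWIST,
                       chain_ids = c("A", "B"), phase = 0) {
  fiber_duplex(sequence, rise = rise, twist = twist,
               chain_ids = chain_ids, phase = phase)
}

#' Specification of a nucleosome-like superhelical duplex
#'
#' @param n_bp number of base pairs (146 for the nucleosome-like fixture).
#' @param modulation_period period of the imposed minor-groove width
#'   modulation, bp.
#' @param modulation_amplitude sinusoid amplitude of the modulation, Angstrom
#'   (half the peak-to-trough excursion).
#' @param superhelix_radius,pitch superhelical path radius and pitch, Angstrom.
#' @param sequence optional explicit sequence; default repeats the 22-mer
#'   d(CGCGAATTCGCGCGAATTCGCG) to length.
#' @export
superhelix_spec <- function(n_bp = 146L, modulation_period = 10,
                            modulation_amplitude = 2,
                            superhelix_radius = 42, pitch = 26,
                            sequence = NULL) {
  if (modulation_period < 2) stop_dnacage("modulation_period must be >= 2 bp")
  if (modulation_amplitude < 0) stop_dnacage("modulation_amplitude must be >= 0")
  if (n_bp < 2 * modulation_period)
    stop_dnacage("n_bp must be at least twice the modulation period")
  if (is.null(sequence)) {
    base <- "CGCGAATTCGCGCGAATTCGCG"
    sequence <- substr(strrep(base, ceiling(n_bp / nchar(base))), 1L, n_bp)
  }
  structure(list(n_bp = as.integer(n_bp), modulation_period = modulation_period,
                 modulation_amplitude = modulation_amplitude,
                 superhelix_radius = superhelix_radius, pitch = pitch,
                 sequence = sequence), class = "superhelix_spec")
}

#' Build a superhelically bent duplex with modulated minor-groove width
#'
#' Bends a fiber-model duplex onto a superhelical path (radius/pitch as in a
#' nucleosome core particle, where successive gyres run roughly parallel at
#' an axial separation equal to the pitch) and calibrates the cross-strand
#' phosphate geometry so that the minor-groove width follows
#' `W0 - A * cos(2 * pi * (bp - 1) / period)`. The calibration iteratively
#' adjusts the per-bp backbone gap angle against the package's own
#' groove-width analyzer, which also cancels the width distortion introduced
#' by the path curvature; with `modulation_amplitude = 0` the profile is flat.
#'
#' @param spec a [superhelix_spec()].
#' @param rise,twist helical parameters as in [build_bdna()].
#' @return a `"molsys"` holding the bent duplex.
#' @export
build_superhelix <- function(spec, rise = BDNA_RISE, twist = BDNA_TWIST) {
  stopifnot(inherits(spec, "superhelix_spec"))
  n <- spec$n_bp
  frames <- superhelix_frames(n, rise, spec$superhelix_radius, spec$pitch)
  # mean raw width of the unmodulated straight fiber + sensitivity to phi0
  w_of_phi <- function(phi) {
    sys <- fiber_duplex(strrep("A", 24L), rise, twist, phi0 = phi)
    w <- groove_widths(single_frame_traj(sys), sys$duplexes[[1L]])
    mean(w$minor_width, na.rm = TRUE)
  }
  w0 <- w_of_phi(BDNA_PHI0)
  slope <- (w_of_phi(BDNA_PHI0 + 2) - w_of_phi(BDNA_PHI0 - 2)) / 4  # A/deg
  if (spec$modulation_amplitude >= w0)
    stop_dnacage("modulation_amplitude (%.1f A) must be below the mean minor width (%.1f A)",
                 spec$modulation_amplitude, w0)
  target <- w0 - spec$modulation_amplitude *
    cos(2 * pi * (seq_len(n) - 1) / spec$modulation_period)
  phi <- rep(BDNA_PHI0, n)
  sys <- NULL
  for (iter in 1:8) {
    sys <- fiber_duplex(spec$sequence, rise, twist, phi0 = phi, frames = frames)
    w <- groove_widths(single_frame_traj(sys), sys$duplexes[[1L]])$minor_width
    err <- w - target
    err[is.na(err)] <- 0
    if (max(abs(err)) < 0.05) break
    phi <- phi - 0.7 * err / slope
  }
  sys
}

# One-frame trajectory wrapping a system's stored coordinates (internal).
single_frame_traj <- function(system, time = 0) {
  xyz <- array(atom_xyz(system$atoms), dim = c(nrow(system$atoms), 3L, 1L))
  new_trajectory(xyz, times = time, topology = system)
}

# ---- spermidine template ----------------------------------------------------

SPD_BOND <- 1.5       # A, uniform heavy-atom bond length
SPD_ANGLE <- 112      # degrees, backbone valence angle

#' All-trans spermidine template coordinates
#'
#' Planar zig-zag chain N1-C2-C3-C4-N5-C6-C7-C8-C9-N10 with uniform bond
#' length 1.5 A and valence angle 112 degrees, centered on the central
#' nitrogen N5. The all-trans end-to-end distance follows in closed form
#' from the chain geometry.
#' @return 10 x 3 matrix with rownames N1, C2, ..., N10.
#' @export
spermidine_template <- function() {
  step <- SPD_BOND * sin(SPD_ANGLE * pi / 360)  # axial advance per bond
  amp <- SPD_BOND * cos(SPD_ANGLE * pi / 360)   # zig-zag half-height
  i <- 0:9
  xyz <- cbind(i * step, 0, amp * (i %% 2))
  rownames(xyz) <- c("N1", "C2", "C3", "C4", "N5", "C6", "C7", "C8", "C9", "N10")
  sweep(xyz, 2L, xyz["N5", ])
}

# Folded (hairpin) template used for conformer fixtures: the second arm of
# the chain is folded back across the central nitrogen so the terminal
# nitrogens approach each other (EE well below the folded threshold).
spermidine_folded_template <- function() {
  xyz <- spermidine_template()
  arm <- xyz[6:10, , drop = FALSE]
  arm[, 1L] <- -arm[, 1L]
  arm[, 3L] <- arm[, 3L] + 1.2
  xyz[6:10, ] <- arm
  xyz
}
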
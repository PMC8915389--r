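# Structure and trajectory input/output. PDB parsing and writing go through
# bio3d; multi-frame data are exchanged as multi-model PDB or CHARMM DCD.
# Ion/water bookkeeping counts and the box travel in REMARK/CRYST1 header
# lines of written structures so a read-back recovers the full composition.

#' Trajectory container
#'
#' Ordered coordinate frames over a constant topology.
#' @param xyz numeric array `n_atoms x 3 x n_frames`, Angstrom.
#' @param times frame times, ns, strictly increasing.
#' @param topology the `"molsys"` the frames refer to.
#' @return object of class `"trajectory"`.
#' @export
new_trajectory <- function(xyz, times, topology) {
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[2L] == 3L)
  if (dim(xyz)[3L] != length(times))
    stop_dnacage("frame count (%d) and time count (%d) differ",
                 dim(xyz)[3L], length(times))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop_dnacage("frame times must be strictly increasing")
  if (dim(xyz)[1L] != nrow(topology$atoms))
    stop_dnacage("frame atom count (%d) does not match topology atom count (%d)",
                 dim(xyz)[1L], nrow(topology$atoms))
  structure(list(xyz = xyz, times = as.numeric(times), topology = topology),
            class = "trajectory")
}

n_frames <- function(traj) dim(traj$xyz)[3L]

#' Coordinates of one frame
#' @param traj a `"trajectory"`.
#' @param i frame index.
#' @return `n_atoms x 3` matrix.
#' @export
frame_xyz <- function(traj, i) traj$xyz[, , i, drop = TRUE]

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %g..%g ns\n",
              n_frames(x), dim(x$xyz)[1L], x$times[1L],
              x$times[n_frames(x)]))
  invisible(x)
}

#' Read a molecular system from a PDB file
#'
#' Parses the file with bio3d, auto-detects DNA duplexes by pairing chains
#' whose sequences are reverse complements, detects polyamines by residue
#' name, and records water/ion counts. Ion and water bookkeeping counts
#' written by [write_structure()] (`REMARK 299 DNACAGE` lines) and a CRYST1
#' box are recovered when present.
#'
#' @param path PDB file.
#' @param spd_resname residue name identifying the polyamine (default "SPD").
#' @return a `"molsys"`.
#' @export
read_structure <- function(path, spd_resname = "SPD") {
  pdb <- bio3d::read.pdb(path, verbose = FALSE, multi = FALSE)
  a <- pdb$atom
  a$elety <- sub("^OP1$", "O1P", a$elety)
  a$elety <- sub("^OP2$", "O2P", a$elety)
  hdr <- read_pdb_header(path)

  resname <- normalize_resname(a$resid)
  is_dna <- resname %in% names(DNA_RESNAMES)
  is_spd <- a$resid %in% spd_resname
  is_k <- a$resid %in% ION_K
  is_cl <- a$resid %in% ION_CL
  is_water <- a$resid %in% WATER
  is_protein <- a$resid %in% bio3d::aa.table$aa3
  other <- !(is_dna | is_spd | is_k | is_cl | is_water | is_protein)
  if (any(other))
    warn_dnacage("unknown residue(s) classified as 'other': %s",
                 paste(unique(a$resid[other]), collapse = ", "))

  keep <- is_dna | is_spd
  a_keep <- a[keep, , drop = FALSE]
  # renumber residues 1..n per chain, 5'->3' (file order)
  atoms <- atom_table(
    atom_id = seq_len(nrow(a_keep)),
    atom_name = a_keep$elety,
    residue_name = a_keep$resid,
    residue_index = renumber_per_chain(a_keep$chain, a_keep$resno),
    chain_id = ifelse(is.na(a_keep$chain) | a_keep$chain == " ",
                      "X", a_keep$chain),
    xyz = cbind(a_keep$x, a_keep$y, a_keep$z)
  )

  dna_chains <- unique(atoms$chain_id[is_dna[keep]])
  duplexes <- pair_dna_chains(atoms, dna_chains)
  polyamines <- detect_polyamines(atoms, spd_resname)

  molecular_system(
    atoms, duplexes = duplexes, polyamines = polyamines,
    n_K = if (!is.na(hdr$counts[["K"]])) hdr$counts[["K"]] else sum(is_k),
    n_Cl = if (!is.na(hdr$counts[["CL"]])) hdr$counts[["CL"]] else sum(is_cl),
    n_water = if (!is.na(hdr$counts[["WATER"]])) hdr$counts[["WATER"]] else
      length(unique(paste(a$chain, a$resno)[is_water])),
    box = hdr$box
  )
}

renumber_per_chain <- function(chain, resno) {
  key <- paste(chain, resno, sep = "\r")
  out <- integer(length(key))
  for (ch in unique(chain)) {
    i <- chain == ch
    out[i] <- match(key[i], unique(key[i]))
  }
  out
}

read_pdb_header <- function(path) {
  lines <- readLines(path, n = 200L, warn = FALSE)
  counts <- c(K = NA_integer_, CL = NA_integer_, WATER = NA_integer_)
  rem <- grep("^REMARK 299 DNACAGE ", lines, value = TRUE)
  for (r in rem) {
    f <- strsplit(trimws(sub("^REMARK 299 DNACAGE ", "", r)), "\\s+")[[1L]]
    if (length(f) == 2L && f[1L] %in% names(counts))
      counts[f[1L]] <- as.integer(f[2L])
  }
  box <- NULL
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr)) {
    box <- as.numeric(c(substr(cr[1L], 7, 15), substr(cr[1L], 16, 24),
                        substr(cr[1L], 25, 33)))
    if (anyNA(box) || all(box == 1)) box <- NULL  # placeholder CRYST1
  }
  list(counts = counts, box = box)
}

pair_dna_chains <- function(atoms, dna_chains) {
  if (length(dna_chains) == 0L) return(list())
  seqs <- lapply(dna_chains, function(ch)
    chain_sequence(atoms[atoms$chain_id == ch, , drop = FALSE]))
  names(seqs) <- dna_chains
  used <- character(0)
  duplexes <- list()
  for (ch in dna_chains) {
    if (ch %in% used) next
    partner <- NULL
    for (other in setdiff(dna_chains, c(used, ch))) {
      if (length(seqs[[other]]) == length(seqs[[ch]]) &&
          all(seqs[[other]] == revcomp(seqs[[ch]]))) {
        partner <- other
        break
      }
    }
    if (is.null(partner))
      stop_dnacage("DNA chain %s has no complementary partner chain", ch)
    used <- c(used, ch, partner)
    duplexes[[length(duplexes) + 1L]] <- duplex_from_atoms(atoms, ch, partner)
  }
  duplexes
}

detect_polyamines <- function(atoms, spd_resname) {
  sub <- atoms[atoms$residue_name %in% spd_resname, , drop = FALSE]
  if (nrow(sub) == 0L) return(list())
  keys <- unique(paste(sub$chain_id, sub$residue_index, sep = "\r"))
  lapply(seq_along(keys), function(i) {
    parts <- strsplit(keys[i], "\r")[[1L]]
    res <- sub[sub$chain_id == parts[1L] & sub$residue_index == parts[2L], ]
    heavy <- res[grepl("^[CN]", res$atom_name), , drop = FALSE]
    n_rows <- grepl("^N", heavy$atom_name)
    if (sum(n_rows) != 3L)
      stop_dnacage("polyamine %s/%s has %d nitrogen atoms; expected 3",
                   parts[1L], parts[2L], sum(n_rows))
    # terminal vs central N by bonded heavy-atom degree (bond cutoff 1.8 A)
    d <- pair_dists(atom_xyz(heavy), atom_xyz(heavy))
    deg <- rowSums(d > 1e-6 & d < 1.8)
    n_ids <- heavy$atom_id[n_rows]
    n_deg <- deg[n_rows]
    central <- n_ids[which.max(n_deg)]
    terminal <- setdiff(n_ids, central)
    if (length(terminal) != 2L)
      stop_dnacage("polyamine %s/%s: cannot separate terminal from central N",
                   parts[1L], parts[2L])
    polyamine(id = i, atom_ids = heavy$atom_id,
              terminal_N = terminal, central_N = central)
  })
}

#' Write a molecular system to a PDB file
#'
#' Atoms are written through bio3d; the box (CRYST1) and the ion/water
#' bookkeeping counts (`REMARK 299 DNACAGE` lines) are prepended so that
#' [read_structure()] round-trips the composition.
#' @param system a `"molsys"`.
#' @param path output PDB path.
#' @export
write_structure <- function(system, path) {
  a <- system$atoms
  bio3d::write.pdb(file = path, xyz = as.numeric(t(atom_xyz(a))),
                   resno = a$residue_index, resid = a$residue_name,
                   elety = a$atom_name, chain = a$chain_id)
  hdr <- c(
    sprintf("REMARK 299 DNACAGE K %d", system$n_K),
    sprintf("REMARK 299 DNACAGE CL %d", system$n_Cl),
    sprintf("REMARK 299 DNACAGE WATER %d", system$n_water)
  )
  if (!is.null(system$box))
    hdr <- c(hdr, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      system$box[1L], system$box[2L], system$box[3L], 90, 90, 90))
  body <- readLines(path, warn = FALSE)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a coordinate trajectory against a known topology
#'
#' Supports multi-model PDB (`.pdb`) and CHARMM DCD (`.dcd`). Frame times
#' are `(0, 1, 2, ...) * frame_dt` ns unless `times` is given explicitly.
#'
#' @param system topology `"molsys"` whose atom count the frames must match.
#' @param path trajectory file.
#' @param frame_dt frame interval, ns.
#' @param times optional explicit frame times, ns.
#' @return a `"trajectory"`.
#' @export
read_trajectory <- function(system, path, frame_dt = 1, times = NULL) {
  ext <- tolower(tools::file_ext(path))
  nat <- nrow(system$atoms)
  if (ext == "dcd") {
    m <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(path, verbose = FALSE, multi = TRUE)
    m <- pdb$xyz
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  }
  nf <- nrow(m)
  if (nf == 0L || ncol(m) == 0L)
    stop_dnacage("trajectory file %s contains no frames", path)
  if (ncol(m) != 3L * nat)
    stop_dnacage("trajectory atom count (%d) does not match topology atom count (%d)",
                 ncol(m) / 3L, nat)
  xyz <- array(0, dim = c(nat, 3L, nf))
  for (f in seq_len(nf))
    xyz[, , f] <- matrix(m[f, ], ncol = 3L, byrow = TRUE)
  if (is.null(times)) times <- (seq_len(nf) - 1L) * frame_dt
  new_trajectory(xyz, times, system)
}

#' Write a trajectory
#'
#' Format chosen by extension: `.pdb` writes a multi-model PDB, `.dcd` a
#' CHARMM-format DCD (readable by bio3d and common MD viewers).
#' @param traj a `"trajectory"`.
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  ext <- tolower(tools::file_ext(path))
  nf <- n_frames(traj)
  if (ext == "dcd") {
    frames <- lapply(seq_len(nf), function(f) frame_xyz(traj, f))
    write_dcd(path, frames, cell = traj$topology$box)
  } else {
    a <- traj$topology$atoms
    m <- t(vapply(seq_len(nf),
                  function(f) as.numeric(t(frame_xyz(traj, f))),
                  numeric(3L * nrow(a))))
    bio3d::write.pdb(file = path, xyz = m, resno = a$residue_index,
                     resid = a$residue_name, elety = a$atom_name,
                     chain = a$chain_id)
  }
  invisible(path)
}

# Minimal CHARMM DCD writer (little-endian, Fortran record markers).
write_dcd <- function(path, frames, cell = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(payload) {
    writeBin(as.integer(length(payload)), con, size = 4L, endian = "little")
    writeBin(payload, con)
    writeBin(as.integer(length(payload)), con, size = 4L, endian = "little")
  }
  as_raw <- function(writer) {
    tmp <- rawConnection(raw(0), "wb")
    writer(tmp)
    out <- rawConnectionValue(tmp)
    close(tmp)
    out
  }
  nf <- length(frames)
  nat <- nrow(frames[[1L]])
  icntrl <- integer(20L)
  icntrl[c(1L, 2L, 3L, 4L)] <- c(nf, 1L, 1L, nf)
  icntrl[11L] <- if (is.null(cell)) 0L else 1L
  icntrl[20L] <- 24L
  rec(c(charToRaw("CORD"), as_raw(function(tmp) {
    writeBin(icntrl[1:9], tmp, size = 4L, endian = "little")
    writeBin(1.0, tmp, size = 4L, endian = "little")
    writeBin(icntrl[11:20], tmp, size = 4L, endian = "little")
  })))
  rec(as_raw(function(tmp) {
    writeBin(1L, tmp, size = 4L, endian = "little")
    writeBin(charToRaw(formatC("written by dnacage", width = 80)), tmp)
  }))
  rec(as_raw(function(tmp)
    writeBin(as.integer(nat), tmp, size = 4L, endian = "little")))
  for (fr in frames) {
    if (!is.null(cell))
      rec(as_raw(function(tmp)
        writeBin(c(cell[1L], 90, cell[2L], 90, 90, cell[3L]), tmp,
                 size = 8L, endian = "little")))
    for (k in 1:3)
      rec(as_raw(function(tmp)
        writeBin(as.numeric(fr[, k]), tmp, size = 4L, endian = "little")))
  }
  invisible(path)
}
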
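# Domain containers: atom tables, duplexes, polyamines, molecular systems,
# and region selections.

DNA_RESNAMES <- c(DA = "A", DT = "T", DG = "G", DC = "C",
                  A = "A", T = "T", G = "G", C = "C",
                  ADE = "A", THY = "T", GUA = "G", CYT = "C")
ION_K  <- c("K", "K+", "POT", "KCL")
ION_CL <- c("CL", "CL-", "CLA")
WATER  <- c("HOH", "WAT", "SOL", "TIP3", "TIP", "SPC")

MINOR_ATOMS <- c("N3", "N2", "O2")
MAJOR_ATOMS <- c("C8", "N7", "C5", "O6", "N4", "C6")
PHOSPHATE_O <- c("O1P", "O2P")
REGION_TAGS <- c("minor", "major", "phosphate", "P", "bp_center",
                 "polyamine_heavy")

complement_base <- function(b) c(A = "T", T = "A", C = "G", G = "C")[b]

revcomp <- function(seq_chars) rev(unname(complement_base(seq_chars)))

#' Create an atom table
#'
#' Builds the canonical atom `data.frame` used throughout the package: one row
#' per atom with identifier, PDB-style atom name, residue name/index, chain
#' and Cartesian coordinates in Angstrom.
#' @param atom_id integer vector.
#' @param atom_name character vector of PDB atom names (e.g. "P", "O1P", "N1").
#' @param residue_name,residue_index,chain_id residue bookkeeping; residue
#'   indices are 1-based per chain, 5' to 3'.
#' @param xyz n x 3 numeric matrix, Angstrom.
#' @return data.frame with columns atom_id, atom_name, residue_name,
#'   residue_index, chain_id, x, y, z.
#' @export
atom_table <- function(atom_id, atom_name, residue_name, residue_index,
                       chain_id, xyz) {
  xyz <- coord_matrix(xyz)
  stopifnot(length(atom_id) == nrow(xyz))
  if (any(!is.finite(xyz))) stop_dnacage("atom coordinates must be finite")
  if (any(!nzchar(atom_name))) stop_dnacage("atom_name must be non-empty")
  data.frame(
    atom_id = as.integer(atom_id),
    atom_name = as.character(atom_name),
    residue_name = as.character(residue_name),
    residue_index = as.integer(residue_index),
    chain_id = as.character(chain_id),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    stringsAsFactors = FALSE
  )
}

atom_xyz <- function(atoms, ids = NULL) {
  if (!is.null(ids)) atoms <- atoms[match(ids, atoms$atom_id), , drop = FALSE]
  as.matrix(atoms[, c("x", "y", "z")])
}

#' Construct a duplex description from an atom table
#'
#' Pairs two complementary antiparallel chains into a duplex record holding
#' the base-pair list, per-base-pair center atoms (the purine N1 of each
#' pair) and per-strand phosphate atom ids. Base pair `b` consists of residue
#' `b` of the first chain and residue `n + 1 - b` of the second.
#'
#' @param atoms atom table (see [atom_table()]).
#' @param chain_i,chain_ii chain identifiers of strand I and strand II.
#' @return object of class `"duplex"`.
#' @export
duplex_from_atoms <- function(atoms, chain_i, chain_ii) {
  sub_i <- atoms[atoms$chain_id == chain_i, , drop = FALSE]
  sub_ii <- atoms[atoms$chain_id == chain_ii, , drop = FALSE]
  seq_i <- chain_sequence(sub_i)
  seq_ii <- chain_sequence(sub_ii)
  n <- length(seq_i)
  if (n != length(seq_ii))
    stop_dnacage("chains %s and %s differ in length (%d vs %d nt)",
                 chain_i, chain_ii, n, length(seq_ii))
  if (!all(seq_ii == revcomp(seq_i)))
    stop_dnacage("chains %s and %s are not Watson-Crick complementary",
                 chain_i, chain_ii)
  bp <- seq_len(n)
  res_ii <- n + 1L - bp
  bp_center <- integer(n)
  for (b in bp) {
    if (seq_i[b] %in% c("A", "G")) {
      bp_center[b] <- residue_atom_id(sub_i, b, "N1")
    } else {
      bp_center[b] <- residue_atom_id(sub_ii, res_ii[b], "N1")
    }
  }
  if (anyNA(bp_center))
    stop_dnacage("duplex %s/%s: purine N1 missing for base pair(s) %s",
                 chain_i, chain_ii,
                 paste(bp[is.na(bp_center)], collapse = ","))
  phos <- list(
    I = strand_phosphates(sub_i, bp, bp),
    II = strand_phosphates(sub_ii, res_ii, bp)
  )
  structure(list(
    sequence = paste(seq_i, collapse = ""),
    chains = c(I = chain_i, II = chain_ii),
    base_pairs = data.frame(bp = bp, res_i = bp, res_ii = res_ii),
    bp_center_id = bp_center,
    phos = phos
  ), class = "duplex")
}

chain_sequence <- function(sub) {
  res <- sub[!duplicated(sub$residue_index), c("residue_index", "residue_name")]
  res <- res[order(res$residue_index), ]
  bases <- DNA_RESNAMES[normalize_resname(res$residue_name)]
  if (anyNA(bases))
    stop_dnacage("non-nucleotide residue(s) in DNA chain: %s",
                 paste(unique(res$residue_name[is.na(bases)]), collapse = ","))
  unname(bases)
}

# Strip terminal-residue suffixes such as DA5/DA3 and map OP1/OP2 upstream.
normalize_resname <- function(x) sub("[35]$", "", x)

residue_atom_id <- function(sub, resno, name) {
  hit <- sub$atom_id[sub$residue_index == resno & sub$atom_name == name]
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

# Per-strand phosphate table indexed by base-pair number.
strand_phosphates <- function(sub, resnos, bps) {
  p <- vapply(resnos, function(r) residue_atom_id(sub, r, "P"), integer(1L))
  o1 <- vapply(resnos, function(r) residue_atom_id(sub, r, "O1P"), integer(1L))
  o2 <- vapply(resnos, function(r) residue_atom_id(sub, r, "O2P"), integer(1L))
  data.frame(bp = bps, res = resnos, P = p, O1P = o1, O2P = o2)
}

n_bp <- function(duplex) nrow(duplex$base_pairs)

duplex_atom_ids <- function(system, duplex) {
  system$atoms$atom_id[system$atoms$chain_id %in% duplex$chains]
}

#' Assemble a molecular system
#'
#' @param atoms atom table.
#' @param duplexes list of `"duplex"` objects.
#' @param polyamines list of `"polyamine"` objects.
#' @param n_K,n_Cl,n_water bookkeeping counts of potassium, chloride and
#'   water (ions and water are counted, never instantiated as atoms).
#' @param box length-3 numeric of orthorhombic box edges (Angstrom) or NULL.
#' @return object of class `"molsys"`.
#' @export
molecular_system <- function(atoms, duplexes = list(), polyamines = list(),
                             n_K = 0L, n_Cl = 0L, n_water = 0L, box = NULL) {
  structure(list(
    atoms = atoms, duplexes = duplexes, polyamines = polyamines,
    n_K = as.integer(n_K), n_Cl = as.integer(n_Cl),
    n_water = as.integer(n_water),
    box = if (is.null(box)) NULL else as.numeric(box)
  ), class = "molsys")
}

#' Polyamine record
#'
#' A linear triamine (spermidine-like) molecule: three nitrogens, two
#' terminal and one central, identified by bonding topology rather than by
#' file atom names.
#' @param id molecule identifier.
#' @param atom_ids ids of all heavy atoms, in chain order when known.
#' @param terminal_N ids of the two terminal nitrogens.
#' @param central_N id of the secondary (central) nitrogen.
#' @param formal_charge integer charge, +3 for spermidine.
#' @export
polyamine <- function(id, atom_ids, terminal_N, central_N, formal_charge = 3L) {
  if (length(terminal_N) != 2L || length(central_N) != 1L)
    stop_dnacage("polyamine %s: need 2 terminal and 1 central nitrogen", id)
  if (central_N %in% terminal_N)
    stop_dnacage("polyamine %s: central N coincides with a terminal N", id)
  structure(list(
    id = id, atom_ids = as.integer(atom_ids),
    terminal_N = as.integer(terminal_N), central_N = as.integer(central_N),
    formal_charge = as.integer(formal_charge)
  ), class = "polyamine")
}

#' Net formal charge of a system
#'
#' Formal charge accounting: -1 per backbone phosphate, +`formal_charge` per
#' polyamine, +1 per K, -1 per Cl. Systems built to the reference
#' stoichiometries are neutral.
#' @param system a `"molsys"`.
#' @return integer net charge.
#' @export
total_charge <- function(system) {
  n_p <- sum(vapply(system$duplexes, function(d) {
    sum(!is.na(d$phos$I$P)) + sum(!is.na(d$phos$II$P))
  }, integer(1L)))
  q_pa <- sum(vapply(system$polyamines, `[[`, integer(1L), "formal_charge"))
  -n_p + q_pa + system$n_K - system$n_Cl
}

#' Select analysis reference atoms of a DNA region
#'
#' Region definitions (by PDB atom name within the duplex):
#' minor groove `N3, N2, O2`; major groove `C8, N7, C5, O6, N4, C6`;
#' `phosphate` the O1P and O2P oxygens; `P` the backbone phosphorus atoms;
#' `bp_center` one purine N1 per base pair; `polyamine_heavy` all C and N
#' atoms of the polyamines (no hydrogens).
#'
#' @param system a `"molsys"`.
#' @param duplex a `"duplex"` of `system` (ignored for `polyamine_heavy`).
#' @param region_tag one of `"minor"`, `"major"`, `"phosphate"`, `"P"`,
#'   `"bp_center"`, `"polyamine_heavy"`.
#' @return object of class `"region_selection"`: `region_tag` plus the
#'   selected `atom_ids`.
#' @export
select_region <- function(system, duplex = NULL, region_tag) {
  if (!region_tag %in% REGION_TAGS)
    stop_dnacage("unknown region_tag '%s'; valid tags: %s",
                 region_tag, paste(REGION_TAGS, collapse = ", "))
  ids <- switch(region_tag,
    polyamine_heavy = {
      unlist(lapply(system$polyamines, function(p) {
        a <- system$atoms[match(p$atom_ids, system$atoms$atom_id), ]
        a$atom_id[grepl("^[CN]", a$atom_name)]
      }), use.names = FALSE)
    },
    bp_center = duplex$bp_center_id,
    P = {
      ids <- c(duplex$phos$I$P, duplex$phos$II$P)
      ids[!is.na(ids)]
    },
    phosphate = {
      ids <- c(duplex$phos$I$O1P, duplex$phos$I$O2P,
               duplex$phos$II$O1P, duplex$phos$II$O2P)
      ids[!is.na(ids)]
    },
    {
      names_wanted <- if (region_tag == "minor") MINOR_ATOMS else MAJOR_ATOMS
      sub <- system$atoms[system$atoms$chain_id %in% duplex$chains, ]
      sub$atom_id[sub$atom_name %in% names_wanted]
    })
  if (length(ids) == 0L)
    stop_dnacage("region '%s' selected no atoms", region_tag)
  structure(list(region_tag = region_tag, atom_ids = as.integer(ids)),
            class = "region_selection")
}

# Region atoms of a single base pair (minor/major/phosphate), used by
# per-residue coordination profiles.
bp_region_ids <- function(system, duplex, bp, region_tag) {
  if (region_tag == "phosphate") {
    ids <- c(duplex$phos$I[duplex$phos$I$bp == bp, c("O1P", "O2P")],
             duplex$phos$II[duplex$phos$II$bp == bp, c("O1P", "O2P")])
    ids <- unlist(ids, use.names = FALSE)
    return(ids[!is.na(ids)])
  }
  names_wanted <- if (region_tag == "minor") MINOR_ATOMS else MAJOR_ATOMS
  resmap <- duplex$base_pairs[duplex$base_pairs$bp == bp, ]
  sub <- system$atoms
  hit_i <- sub$chain_id == duplex$chains[["I"]] &
    sub$residue_index == resmap$res_i & sub$atom_name %in% names_wanted
  hit_ii <- sub$chain_id == duplex$chains[["II"]] &
    sub$residue_index == resmap$res_ii & sub$atom_name %in% names_wanted
  sub$atom_id[hit_i | hit_ii]
}

#' @export
print.molsys <- function(x, ...) {
  cat(sprintf("Molecular system: %d atoms, %d duplex(es), %d polyamine(s)\n",
              nrow(x$atoms), length(x$duplexes), length(x$polyamines)))
  for (d in x$duplexes)
    cat(sprintf("  duplex %s/%s: %d bp, 5'-%s-3'\n",
                d$chains[["I"]], d$chains[["II"]], n_bp(d), d$sequence))
  cat(sprintf("  ions: %d K+, %d Cl-; %d water (bookkeeping)\n",
              x$n_K, x$n_Cl, x$n_water))
  if (!is.null(x$box))
    cat(sprintf("  box: %.1f x %.1f x %.1f A\n", x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  net formal charge: %+d\n", total_charge(x)))
  invisible(x)
}

#' @export
print.duplex <- function(x, ...) {
  cat(sprintf("DNA duplex %s/%s: %d bp, 5'-%s-3'\n",
              x$chains[["I"]], x$chains[["II"]], n_bp(x), x$sequence))
  invisible(x)
}
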
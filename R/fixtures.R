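# Synthetic toy complexes with planted electrostatic group structure.
#
# Each toy complex is a neutral scaffold slab of pseudo-atoms (the MHC
# stand-in, identical across all fixtures) plus a row of nine charged
# pseudo-residues along x in the cleft plane (the nonamer peptide stand-in).
# Because the scaffold is shared and neutral, all similarity differences are
# attributable to the peptide charge motif, mirroring the focus-region
# rationale of comparing only the cleft. Pseudo-residue names encode charge
# levels (Q00, Q01, ...); the actual charges live in a generated charge
# table, keeping fixture truth decoupled from the biological charge model.

#' Charge motif specification for a toy complex
#'
#' @param charges Numeric length-9 vector of per-position charges (e).
#' @param jitter Coordinate noise s.d. applied to peptide atoms (Angstrom,
#'   >= 0).
#' @param group Group identifier (any scalar).
#' @export
motif_spec <- function(charges, jitter = 0, group = NA) {
  charges <- as.numeric(charges)
  if (length(charges) != 9) abort("a motif has exactly 9 positions (nonamer)")
  if (jitter < 0) abort("jitter must be >= 0")
  structure(list(charges = charges, jitter = jitter, group = group),
            class = "mep_motif")
}

# charge-level coding shared across a fixture set: value -> residue name
.charge_levels <- function(values) {
  lv <- sort(unique(values))
  tibble(residue_name = sprintf("Q%02d", seq_along(lv) - 1L), charge = lv)
}

#' Charge-model rows for fixture pseudo-residues
#'
#' @param motifs List of [motif_spec()] objects (levels are shared across
#'   all of them).
#' @return Tibble (`residue_name`, `atom_name`, `charge`, `radius`) suitable
#'   for the `extra` argument of [default_charge_model()], including the
#'   neutral scaffold residue `SCF`.
#' @export
fixture_charge_table <- function(motifs) {
  lv <- .charge_levels(unlist(lapply(motifs, function(m) m$charges)))
  dplyr::bind_rows(
    tibble(residue_name = "SCF", atom_name = "CA", charge = 0, radius = 1.7),
    tibble(residue_name = lv$residue_name, atom_name = "CA",
           charge = lv$charge, radius = 1.7))
}

# scaffold: 8 x 8 slab of neutral pseudo-atoms 4 A below the cleft plane
.scaffold_atoms <- function() {
  g <- expand.grid(i = 0:7, j = 0:7)
  tibble(record_type = "ATOM",
         serial = seq_len(nrow(g)),
         atom_name = "CA",
         residue_name = "SCF",
         chain_id = "A",
         residue_number = seq_len(nrow(g)),
         x = (g$i - 3.5) * 3.8,
         y = (g$j - 3.5) * 3.8,
         z = -4)
}

#' Generate one toy pMHC-like complex
#'
#' Deterministic given (motif, seed): the scaffold is fixed; the nine
#' peptide pseudo-residues sit at 3.8 Angstrom spacing along x at the cleft
#' plane (z = 0), carrying the motif charges, jittered by the motif's noise
#' level. The peptide chain is the shortest chain with 9 residues, so
#' automatic cleft placement works on the result.
#'
#' @param motif A [motif_spec()].
#' @param seed Integer seed for the jitter.
#' @param label Complex identifier.
#' @param levels Optional shared charge-level table (from
#'   [.charge_levels()] internals via [fixture_charge_table()]); defaults to
#'   levels derived from this motif alone.
#' @return A `mep_structure` with charges and radii already assigned; the
#'   matching charge-table rows are attached as attribute `charge_table`.
#' @export
generate_toy_complex <- function(motif, seed = 1, label = "toy",
                                 levels = NULL) {
  stopifnot(inherits(motif, "mep_motif"))
  if (is.null(levels)) levels <- .charge_levels(motif$charges)
  resname <- levels$residue_name[match(motif$charges, levels$charge)]
  if (anyNA(resname)) abort("motif charges missing from the shared levels")

  scaf <- .scaffold_atoms()
  pep <- tibble(record_type = "ATOM",
                serial = nrow(scaf) + 1:9,
                atom_name = "CA",
                residue_name = resname,
                chain_id = "C",
                residue_number = 1:9,
                x = ((1:9) - 5) * 3.8,
                y = 0,
                z = 0)
  if (motif$jitter > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(seed %% 2147483647L)
    noise <- matrix(stats::rnorm(27, sd = motif$jitter), 9, 3)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    pep$x <- round(pep$x + noise[, 1], 3)
    pep$y <- round(pep$y + noise[, 2], 3)
    pep$z <- round(pep$z + noise[, 3], 3)
  }
  atoms <- dplyr::bind_rows(scaf, pep)
  atoms$charge <- c(rep(0, nrow(scaf)), motif$charges)
  atoms$radius <- 1.7
  s <- new_structure(atoms, label)
  attr(s, "charge_table") <- fixture_charge_table(list(motif))
  s
}

#' Generate a benchmark set with planted groups
#'
#' Group motifs are orthogonal by construction: group g places charges
#' (+s, -s, +s, ...) on its own block of `floor(9 / n_groups)` peptide
#' positions and zero elsewhere, where s is `motif_separation`. Members of a
#' group differ only by coordinate jitter. PDB files, a truth-label TSV and
#' the fixture charge table are written to `dir`.
#'
#' @param n_groups Number of planted groups (>= 2, <= 9).
#' @param per_group Complexes per group (>= 2; total >= 3).
#' @param motif_separation Charge magnitude s in e (default 1).
#' @param jitter Peptide coordinate noise s.d., Angstrom (default 0.2).
#' @param seed Master seed.
#' @param dir Output directory (created); `NULL` for structures only.
#' @return List: `structures` (list of `mep_structure`), `truth` (tibble
#'   `label`, `group`), `charge_table`, `files` (paths or `NULL`).
#' @export
generate_benchmark_set <- function(n_groups = 3, per_group = 3,
                                   motif_separation = 1, jitter = 0.2,
                                   seed = 1, dir = NULL) {
  if (n_groups < 2 || per_group < 2 || n_groups * per_group < 3) {
    abort("need n_groups >= 2, per_group >= 2 and at least 3 complexes")
  }
  block <- floor(9 / n_groups)
  if (block < 1) {
    abort("infeasible separation request: more groups than peptide positions")
  }
  motifs <- lapply(seq_len(n_groups), function(g) {
    ch <- numeric(9)
    pos <- ((g - 1) * block + 1):(g * block)
    ch[pos] <- motif_separation * (-1)^(seq_along(pos) - 1)
    motif_spec(ch, jitter = jitter, group = g)
  })
  charge_table <- fixture_charge_table(motifs)
  lv <- .charge_levels(unlist(lapply(motifs, function(m) m$charges)))

  structures <- list()
  truth <- list()
  k <- 0
  for (g in seq_len(n_groups)) {
    for (m in seq_len(per_group)) {
      k <- k + 1
      label <- sprintf("g%d_m%d", g, m)
      structures[[k]] <- generate_toy_complex(
        motifs[[g]], seed = (seed * 131 + k * 17) %% 2147483647L,
        label = label, levels = lv)
      truth[[k]] <- tibble(label = label, group = g)
    }
  }
  truth <- dplyr::bind_rows(truth)

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- vapply(structures, function(s) {
      p <- file.path(dir, paste0(structure_label(s), ".pdb"))
      write_structure(s, p)
      p
    }, character(1))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(charge_table, file.path(dir, "charge_model.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(structures = structures, truth = truth,
       charge_table = charge_table, files = files)
}

#' The shipped synthetic reference frame
#'
#' A zero-jitter, zero-charge toy complex in the canonical frame (cleft
#' plane = xy, peptide axis = x, cleft centroid = origin), used as the
#' default superposition reference. Any user PDB can be supplied instead.
#'
#' @return A `mep_structure`.
#' @export
reference_structure <- function() {
  generate_toy_complex(motif_spec(numeric(9), jitter = 0), seed = 1,
                       label = "reference")
}
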
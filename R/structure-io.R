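#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

# Column layout of an atom table. Coordinates in Angstrom, charge in
# elementary charges, radius in Angstrom.
.atom_cols <- c("record_type", "serial", "atom_name", "residue_name",
                "chain_id", "residue_number", "x", "y", "z",
                "charge", "radius")

#' Construct a structure object from an atom table
#'
#' A structure is a tibble of atom records (one row per atom, in file order)
#' carrying a `label` attribute that identifies the complex within a run.
#'
#' @param atoms Data frame with columns `record_type` ("ATOM" or "HETATM"),
#'   `serial`, `atom_name`, `residue_name`, `chain_id`, `residue_number`,
#'   `x`, `y`, `z` (Angstrom) and optionally `charge` (e) and `radius`
#'   (Angstrom); missing charge/radius columns default to 0.
#' @param label Character scalar identifying the complex.
#' @return A tibble of class `mep_structure`.
#' @export
new_structure <- function(atoms, label) {
  atoms <- as_tibble(atoms)
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  if (!"radius" %in% names(atoms)) atoms$radius <- 0
  missing <- setdiff(.atom_cols, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("atom table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  atoms <- atoms[, .atom_cols]
  if (nrow(atoms) == 0) abort("a structure must contain at least one atom")
  if (!all(atoms$record_type %in% c("ATOM", "HETATM"))) {
    abort("record_type must be 'ATOM' or 'HETATM'")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("all atom coordinates must be finite")
  }
  if (any(atoms$radius < 0)) abort("atom radii must be >= 0")
  structure(atoms,
            class = c("mep_structure", class(tibble())),
            label = as.character(label))
}

#' @export
print.mep_structure <- function(x, ...) {
  cat("<mep_structure> label:", attr(x, "label"),
      "-", nrow(x), "atoms,",
      length(unique(x$chain_id)), "chain(s)\n")
  NextMethod()
}

#' Label of a structure
#' @param s A `mep_structure`.
#' @return Character scalar.
#' @export
structure_label <- function(s) attr(s, "label")

#' Coordinates of a structure as a numeric matrix
#' @param s A `mep_structure`.
#' @return n x 3 matrix (Angstrom), unnamed.
#' @export
coords <- function(s) unname(cbind(s$x, s$y, s$z))

.is_coord_record <- function(lines) {
  rec <- substr(lines, 1, 6)
  trimws(rec) %in% c("ATOM", "HETATM") |
    grepl("^\\s*(ATOM|HETATM)\\s", lines)
}

# Parse one fixed-column PDB v3.3 coordinate line. Returns NULL on failure.
.parse_fixed <- function(line) {
  if (nchar(line) < 54) return(NULL)
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                       substr(line, 39, 46),
                                       substr(line, 47, 54))))
  serial <- suppressWarnings(as.integer(substr(line, 7, 11)))
  resno <- suppressWarnings(as.integer(substr(line, 23, 26)))
  if (anyNA(xyz) || is.na(serial) || is.na(resno)) return(NULL)
  list(record_type = trimws(substr(line, 1, 6)),
       serial = serial,
       atom_name = trimws(substr(line, 13, 16)),
       altloc = substr(line, 17, 17),
       residue_name = trimws(substr(line, 18, 20)),
       chain_id = trimws(substr(line, 22, 22)),
       residue_number = resno,
       x = xyz[1], y = xyz[2], z = xyz[3])
}

# Parse one whitespace-delimited nine-field record (the stripped dialect).
.parse_nine <- function(line) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(f) != 9) return(NULL)
  xyz <- suppressWarnings(as.numeric(f[7:9]))
  serial <- suppressWarnings(as.integer(f[2]))
  resno <- suppressWarnings(as.integer(f[6]))
  if (anyNA(xyz) || is.na(serial) || is.na(resno)) return(NULL)
  list(record_type = f[1], serial = serial, atom_name = f[3],
       altloc = " ", residue_name = f[4], chain_id = f[5],
       residue_number = resno, x = xyz[1], y = xyz[2], z = xyz[3])
}

#' Parse a PDB structure
#'
#' Reads either standard fixed-column PDB (v3.3 coordinate section) or the
#' whitespace-delimited nine-field dialect produced by
#' [preprocess_structure_file()]. Non-coordinate records (REMARK, SEQRES,
#' TER, END, ANISOU, CONECT, ...) are ignored. Alternate locations other
#' than ' ' or 'A' are dropped; hydrogens present in the input are kept.
#'
#' @param source Path to a PDB file, or a character vector of lines.
#' @param label Complex identifier; defaults to the file base name.
#' @return A [new_structure()] tibble; `charge` and `radius` are 0 until
#'   [assign_charges_radii()] is called.
#' @export
parse_structure <- function(source, label = NULL) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(source))
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    if (is.null(label)) label <- "structure"
  }
  if (length(lines) == 0) abort("empty structure source")
  keep <- which(.is_coord_record(lines))
  if (length(keep) == 0) abort("no coordinate (ATOM/HETATM) records found")

  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- lines[keep[i]]
    rec <- .parse_fixed(ln)
    if (is.null(rec)) rec <- .parse_nine(ln)
    if (is.null(rec)) {
      abort(sprintf("unparseable coordinate record at line %d: %s",
                    keep[i], trimws(ln)))
    }
    rows[[i]] <- rec
  }
  atoms <- dplyr::bind_rows(rows)
  atoms <- atoms[atoms$altloc %in% c(" ", "", "A"), , drop = FALSE]
  atoms$altloc <- NULL
  if (nrow(atoms) == 0) abort("no atoms left after alternate-location filtering")
  new_structure(atoms, label)
}

#' Write a structure as fixed-column PDB
#'
#' @param s A `mep_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  lines <- sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f",
                   s$record_type, s$serial,
                   ifelse(nchar(s$atom_name) < 4,
                          paste0(" ", s$atom_name), s$atom_name),
                   s$residue_name, s$chain_id, s$residue_number,
                   s$x, s$y, s$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Strip a PDB file down to nine-field coordinate records
#'
#' Sanitizes a PDB-like file: every surviving line is a coordinate record
#' with exactly nine whitespace-separated fields (record type, serial, atom
#' name, residue name, chain id, residue number, x, y, z). All other record
#' types are dropped. The operation is idempotent.
#'
#' @param infile Input PDB path.
#' @param outfile Output path; defaults to `<infile>.clean`.
#' @return `outfile`, invisibly.
#' @export
preprocess_structure_file <- function(infile,
                                      outfile = paste0(infile, ".clean")) {
  s <- parse_structure(infile)
  lines <- sprintf("%s %d %s %s %s %d %.3f %.3f %.3f",
                   s$record_type, s$serial, s$atom_name, s$residue_name,
                   s$chain_id, s$residue_number, s$x, s$y, s$z)
  writeLines(lines, outfile)
  invisible(outfile)
}

#' Default per-atom charge and radius model
#'
#' Loads the shipped charge/radius table: formal charges on titratable side
#' chains (ASP/GLU -1 split over the carboxylate oxygens, LYS NZ +1, ARG +1
#' split over NH1/NH2, HIS 0) plus a C-terminal OXT of -1, and per-element
#' van der Waals radii (C 1.7, N 1.55, O 1.52, S 1.8, H 1.2 Angstrom).
#' N-terminal amines receive +1 during assignment when `add_termini` is on.
#'
#' @param extra Optional data frame of additional rows
#'   (`residue_name`, `atom_name`, `charge`, `radius`) that override the
#'   defaults on matching keys; used e.g. to register synthetic pseudo-atom
#'   types.
#' @param unknown Policy for atoms whose residue is not covered by the
#'   table: `"zero"` assigns charge 0 and a generic 1.7 Angstrom radius,
#'   `"error"` fails listing the offenders.
#' @return A list of class `mep_charge_model`.
#' @export
default_charge_model <- function(extra = NULL, unknown = c("zero", "error")) {
  unknown <- match.arg(unknown)
  path <- system.file("extdata", "charge_model.tsv", package = "mepsim",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  charge_model(tab, extra = extra, unknown = unknown)
}

#' Build a charge model from a table
#'
#' @param table Data frame with columns `residue_name`, `atom_name`,
#'   `charge` (e), `radius` (Angstrom; `NA` = use the element radius).
#' @inheritParams default_charge_model
#' @export
charge_model <- function(table, extra = NULL, unknown = c("zero", "error")) {
  unknown <- match.arg(unknown)
  table <- as_tibble(table)
  if (!is.null(extra)) {
    extra <- as_tibble(extra)
    key <- function(d) paste(d$residue_name, d$atom_name)
    table <- dplyr::bind_rows(table[!key(table) %in% key(extra), ], extra)
  }
  elem_radius <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2, P = 1.8)
  known <- union(unique(table$residue_name),
                 c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                   "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                   "THR", "TRP", "TYR", "VAL", "HOH"))
  structure(list(table = table, elem_radius = elem_radius,
                 known_residues = known, unknown = unknown),
            class = "mep_charge_model")
}

.element_of <- function(atom_name) {
  e <- sub("^[0-9']*", "", atom_name)
  substr(e, 1, 1)
}

#' Assign partial charges and radii to a structure
#'
#' Charges come from the model's (residue, atom) table; atoms of known
#' residues absent from the table are neutral. Radii come from table rows
#' when given, otherwise from the per-element radius table. When
#' `add_termini` is `TRUE`, the backbone N of the first residue of every
#' protein (ATOM) chain gains +1 e (zwitterionic N-terminus); the
#' C-terminal -1 sits on OXT via the table.
#'
#' @param s A `mep_structure`.
#' @param model A `mep_charge_model`; default [default_charge_model()].
#' @param add_termini Apply the N-terminal +1 adjustment (default `TRUE`).
#' @return The structure with `charge` and `radius` populated; atom order
#'   unchanged.
#' @export
assign_charges_radii <- function(s, model = default_charge_model(),
                                 add_termini = TRUE) {
  stopifnot(inherits(model, "mep_charge_model"))
  key <- paste(s$residue_name, s$atom_name)
  tkey <- paste(model$table$residue_name, model$table$atom_name)
  idx <- match(key, tkey)

  unknown_res <- !(s$residue_name %in% model$known_residues)
  if (any(unknown_res) && model$unknown == "error") {
    off <- unique(paste(s$residue_name[unknown_res],
                        s$atom_name[unknown_res]))
    abort(paste0("atoms not resolvable in the charge model: ",
                 paste(off, collapse = ", ")))
  }

  charge <- ifelse(is.na(idx), 0, model$table$charge[idx])
  radius <- model$table$radius[idx]
  elem <- .element_of(s$atom_name)
  fallback <- unname(model$elem_radius[elem])
  fallback[is.na(fallback)] <- 1.7
  radius <- ifelse(is.na(radius), fallback, radius)

  if (add_termini) {
    for (ch in unique(s$chain_id[s$record_type == "ATOM"])) {
      in_ch <- which(s$chain_id == ch & s$record_type == "ATOM")
      first_res <- s$residue_number[in_ch[1]]
      nt <- in_ch[s$residue_number[in_ch] == first_res &
                    s$atom_name[in_ch] == "N"]
      charge[nt] <- charge[nt] + 1
    }
  }
  s$charge <- charge
  s$radius <- radius
  s
}

#' Total charge of a structure
#' @param s A `mep_structure` with charges assigned.
#' @return Net charge in e.
#' @export
total_charge <- function(s) sum(s$charge)

#' Identify the peptide chain
#'
#' The peptide is the shortest chain with 8-11 residues (nonamer epitopes
#' and close lengths), unless overridden.
#'
#' @param s A `mep_structure`.
#' @param override Chain id to use verbatim, or `NULL` for auto-detection.
#' @return Chain id (character scalar).
#' @export
peptide_chain <- function(s, override = NULL) {
  if (!is.null(override)) {
    if (!override %in% s$chain_id) {
      abort(sprintf("chain '%s' not present in structure '%s'",
                    override, structure_label(s)))
    }
    return(override)
  }
  nres <- tapply(s$residue_number, s$chain_id,
                 function(r) length(unique(r)))
  cand <- nres[nres >= 8 & nres <= 11]
  if (length(cand) == 0) {
    abort(sprintf(
      "no peptide chain (8-11 residues) found in structure '%s'; set an override",
      structure_label(s)))
  }
  names(cand)[order(cand, names(cand))][1]
}
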
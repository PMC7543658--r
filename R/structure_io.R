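#' Read a macromolecular coordinate file
#'
#' Parses a PDB (fixed-column) or mmCIF file into a \code{structure_model}:
#' a per-atom table plus the high-resolution data limit \code{d_max} (and
#' \code{s_max = 1/d_max}).  Hydrogen and deuterium atoms are removed, and
#' alternate locations are collapsed to a single conformer per site (highest
#' occupancy wins; ties go to the lexicographically smallest alt-loc id),
#' since both the global mixture analysis and the local occupancy estimators
#' require one B value per atomic site.  Elements missing from the element
#' column are inferred from the atom name.
#'
#' @param path path to a \code{.pdb}/\code{.ent} or \code{.cif}/\code{.mmcif}
#'   file containing at least one atom with a B value.
#' @param d_max_override optional resolution limit in Angstrom; takes
#'   precedence over the file header (headers are occasionally absent or
#'   wrong).  Without an override the limit is read from
#'   \code{REMARK   2 RESOLUTION} (PDB) or the
#'   \code{_reflns.d_resolution_high} / \code{_refine.ls_d_res_high} items
#'   (mmCIF); an error is raised if neither exists.
#'
#' @return An object of class \code{structure_model}: a list with
#'   \itemize{
#'     \item \code{atoms}: data frame with \code{chain_id},
#'       \code{residue_name}, \code{residue_seq}, \code{insertion_code},
#'       \code{atom_name}, \code{alt_loc}, \code{element}, \code{x},
#'       \code{y}, \code{z} (Angstrom), \code{b_iso} (\eqn{\mathrm{\AA}^2}),
#'       \code{occupancy}, \code{is_hetero};
#'     \item \code{d_max}, \code{s_max} (\code{= 1/d_max} to full float
#'       precision), \code{source_path}, \code{metadata}.
#'   }
#'   B values below 0 or occupancies outside [0, 1] trigger a warning but
#'   are kept.
#' @examples
#' \donttest{
#' toy <- build_toy_structure(tempfile(fileext = ".pdb"),
#'                            mixture = sigd_mixture(1, 3.5, 50, 10),
#'                            n_per_domain = 125, d_max = 2.0, seed = 1)
#' m <- read_structure(toy$path)
#' m$s_max  # 0.5
#' }
#' @export
read_structure <- function(path, d_max_override = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  parsed <- suppressWarnings(
    if (is_cif) bio3d::read.cif(path) else bio3d::read.pdb(path))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L) stop("no parsable atoms in '", path, "'")

  ele <- toupper(trimws(as.character(at$elesy)))
  blank <- is.na(ele) | ele == ""
  if (any(blank)) {
    inferred <- suppressWarnings(
      bio3d::atom2ele(at$elety[blank], rescue = TRUE))
    ele[blank] <- toupper(inferred)
  }
  atoms <- data.frame(
    chain_id = as.character(at$chain),
    residue_name = as.character(at$resid),
    residue_seq = as.integer(at$resno),
    insertion_code = ifelse(is.na(at$insert) | at$insert == "", "",
                            as.character(at$insert)),
    atom_name = as.character(at$elety),
    alt_loc = ifelse(is.na(at$alt) | at$alt == "", "",
                     as.character(at$alt)),
    element = ele,
    x = at$x, y = at$y, z = at$z,
    b_iso = as.numeric(at$b),
    occupancy = as.numeric(at$o),
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE)
  atoms$chain_id[is.na(atoms$chain_id)] <- ""
  atoms <- atoms[!is.na(atoms$b_iso), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no atoms with B values in '", path, "'")

  if (any(atoms$b_iso < 0))
    warning(sum(atoms$b_iso < 0), " atom(s) with negative B value")
  bad_occ <- !is.na(atoms$occupancy) &
    (atoms$occupancy < 0 | atoms$occupancy > 1)
  if (any(bad_occ))
    warning(sum(bad_occ), " atom(s) with occupancy outside [0, 1]")

  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no non-hydrogen atoms in '", path, "'")

  # collapse alt-locs: keep the highest-occupancy conformer per site,
  # ties broken by the smallest alt-loc id
  site <- paste(atoms$chain_id, atoms$residue_seq, atoms$insertion_code,
                atoms$residue_name, atoms$atom_name, sep = "\r")
  if (anyDuplicated(site)) {
    o <- order(site, -atoms$occupancy, atoms$alt_loc)
    atoms <- atoms[o, , drop = FALSE]
    atoms <- atoms[!duplicated(site[o]), , drop = FALSE]
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  }
  rownames(atoms) <- NULL

  d_max <- d_max_override
  if (is.null(d_max)) d_max <- parse_resolution(path, is_cif)
  if (is.null(d_max))
    stop("no resolution in '", path, "' header; supply d_max_override")
  stopifnot(is.numeric(d_max), d_max > 0)

  structure(list(atoms = atoms, d_max = d_max, s_max = 1 / d_max,
                 source_path = path, metadata = list()),
            class = "structure_model")
}

parse_resolution <- function(path, is_cif) {
  lines <- readLines(path, warn = FALSE)
  if (is_cif) {
    hits <- grep("_(reflns\\.d_resolution_high|refine\\.ls_d_res_high)",
                 lines, value = TRUE)
    for (h in hits) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(h), "\\s+")[[1]][2]))
      if (!is.na(v) && v > 0) return(v)
    }
  } else {
    hits <- grep("^REMARK\\s+2\\s+RESOLUTION", lines, value = TRUE)
    for (h in hits) {
      rest <- sub("^REMARK\\s+2\\s+RESOLUTION\\.?", "", h)
      m <- regmatches(rest, regexpr("[0-9]+\\.?[0-9]*", rest))
      v <- suppressWarnings(as.numeric(m))
      if (length(v) && !is.na(v) && v > 0) return(v)
    }
  }
  NULL
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "structure_model: %d atoms, d_max = %.2f A (s_max = %.4f 1/A)\n",
    nrow(x$atoms), x$d_max, x$s_max))
  cat(sprintf("  source: %s\n", x$source_path))
  invisible(x)
}

#' Write analysis results to TSV or JSON
#'
#' Writes any of the tabular results of the package (occupancy scans, ligand
#' reports, mode assignments) with a deterministic column order and floats
#' printed with four decimals.  JSON output is a list of row objects (see
#' the README for the schema).
#'
#' @param results a data frame produced by \code{\link{scan_atoms}},
#'   \code{\link{ligand_report}} or \code{\link{assign_modes}} (any data
#'   frame is accepted).
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return invisibly, the path written.
#' @export
write_reports <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(results)
  num <- vapply(df, is.numeric, logical(1))
  if (format == "tsv") {
    out <- df
    out[num] <- lapply(out[num], function(v) sprintf("%.4f", v))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    df[num] <- lapply(df[num], function(v) round(v, 4))
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write a mode-colored copy of a model
#'
#' Writes the model as PDB with every atom's B column replaced by its hard
#' mode label (1-based), so any molecular viewer colouring by B factor shows
#' the mixture clusters.
#'
#' @param model a \code{structure_model}.
#' @param assignment a \code{mode_assignment} from
#'   \code{\link{assign_modes}}, or an integer vector of labels, one per
#'   atom.
#' @param path output PDB path.
#' @return invisibly, the path written.
#' @export
write_mode_colored_model <- function(model, assignment, path) {
  stopifnot(inherits(model, "structure_model"))
  labels <- if (inherits(assignment, "mode_assignment"))
    assignment$hard_labels else as.integer(assignment)
  if (length(labels) != nrow(model$atoms))
    stop("assignment length (", length(labels),
         ") != atom count (", nrow(model$atoms), ")")
  write_model_pdb(model$atoms, as.numeric(labels), model$d_max, path)
  invisible(path)
}

# Shared PDB writer: bio3d fixed-column output plus a REMARK 2 resolution
# header so files round-trip through read_structure.
write_model_pdb <- function(atoms, b, d_max, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = ifelse(atoms$is_hetero, "HETATM", "ATOM"),
    resno = atoms$residue_seq,
    resid = atoms$residue_name,
    eleno = seq_len(nrow(atoms)),
    elety = atoms$atom_name,
    chain = atoms$chain_id,
    insert = ifelse(atoms$insertion_code == "", NA, atoms$insertion_code),
    alt = ifelse(atoms$alt_loc == "", NA, atoms$alt_loc),
    o = atoms$occupancy,
    b = b,
    elesy = atoms$element)
  body <- readLines(path, warn = FALSE)
  hdr <- sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", d_max)
  writeLines(c(hdr, body), path)
  invisible(path)
}
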
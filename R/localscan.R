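#' @title Resolution-dependent relative-occupancy estimators
#'
#' @description
#' Two atoms close in space should have similar ADPs; a dramatic difference
#' suggests a wrong occupancy or a wrong element.  Whether a B-value
#' difference is "dramatic" depends on resolution, so these estimators ask:
#' by how much must the occupancy of a fully occupied comparator atom
#' carrying the environment's B value (\eqn{B_2}) be scaled so that its
#' density matches the scrutinized atom's (\eqn{B_1})?  Both atoms are point
#' Gaussians with scattering factor \eqn{\exp(-B s^2/4)} truncated at
#' \eqn{s_{max} = 1/d_{max}}.
#'
#' \code{occ_peak} matches central peak heights:
#' \deqn{c = \rho_{B_1}(0) / \rho_{B_2}(0)}
#' (see \code{\link{peak_height}}); it is unbounded above as
#' \eqn{B_1 \to 0}.  \code{occ_total} matches total squared density via
#' Parseval's theorem, the least-squares occupancy
#' \deqn{c = \frac{\int_0^{s_{max}} s^2 e^{-(B_1+B_2)s^2/4}\,ds}
#'            {\int_0^{s_{max}} s^2 e^{-B_2 s^2/2}\,ds},}
#' which is bounded by \eqn{2^{3/2} \approx 2.83} (attained only as
#' \eqn{B_1 \to 0} at infinite resolution), so it tends to underestimate
#' true occupancies.  \code{occ_peak_inf} and \code{occ_total_inf} are the
#' \eqn{s_{max} \to \infty} limits, \eqn{(B_2/B_1)^{3/2}} and
#' \eqn{[2 B_2/(B_1+B_2)]^{3/2}}.
#'
#' Values of \eqn{c} well below 1 flag atoms/ligands lighter (or less
#' occupied) than their surroundings; values well above 1 flag heavier atoms
#' (e.g. metals modelled as waters).  These are expressions of local ADP
#' differences, not replacements for refined occupancies.
#'
#' @param b_atom B value of the scrutinized atom (\eqn{B_1}),
#'   \eqn{\mathrm{\AA}^2}.
#' @param b_ref B value of the comparator — typically the median ADP of the
#'   spatial environment (\eqn{B_2}), \eqn{\mathrm{\AA}^2}.
#' @param s_max resolution limit \eqn{1/d_{max}}, \eqn{\mathrm{\AA}^{-1}}.
#' @return relative occupancy \eqn{c} (dimensionless); 1 when
#'   \code{b_atom == b_ref}.
#' @examples
#' occ_total(252, 53, 1 / 1.99)  # high-B ligand vs environment: ~0.21
#' occ_total(7, 15, 1 / 1.6)     # low-B "water": > 1, likely a metal
#' occ_total_inf(0, 50)          # upper bound 2^(3/2)
#' @name occupancy
NULL

check_occ_args <- function(b_atom, b_ref, s_max = 1) {
  if (any(!is.finite(b_atom)) || any(b_atom < 0))
    stop("'b_atom' must be finite and >= 0")
  if (any(!is.finite(b_ref)) || any(b_ref < 0))
    stop("'b_ref' must be finite and >= 0")
  if (any(!is.finite(s_max)) || any(s_max <= 0))
    stop("'s_max' must be > 0")
}

#' @rdname occupancy
#' @export
occ_total <- function(b_atom, b_ref, s_max) {
  check_occ_args(b_atom, b_ref, s_max)
  gauss_s2_integral((b_atom + b_ref) / 4, s_max) /
    gauss_s2_integral(b_ref / 2, s_max)
}

#' @rdname occupancy
#' @export
occ_total_inf <- function(b_atom, b_ref) {
  check_occ_args(b_atom, b_ref)
  if (any(b_atom == 0 & b_ref == 0))
    stop("b_atom and b_ref cannot both be 0")
  (2 * b_ref / (b_atom + b_ref))^1.5
}

#' @rdname occupancy
#' @export
occ_peak <- function(b_atom, b_ref, s_max) {
  check_occ_args(b_atom, b_ref, s_max)
  peak_height(b_atom, s_max) / peak_height(b_ref, s_max)
}

#' @rdname occupancy
#' @export
occ_peak_inf <- function(b_atom, b_ref) {
  check_occ_args(b_atom, b_ref)
  if (any(b_atom <= 0)) stop("'b_atom' must be > 0 for the limiting form")
  (b_ref / b_atom)^1.5
}

residue_key <- function(atoms) {
  paste(atoms$chain_id, atoms$residue_seq, atoms$insertion_code, sep = "\r")
}

# All-pairs neighbor search within `radius` using a uniform cell grid
# (cells of side `radius`; only the 27 surrounding cells are scanned).
# Returns a list of integer index vectors, one per atom, excluding self.
neighbor_lists <- function(xyz, radius) {
  n <- nrow(xyz)
  cell <- floor(sweep(xyz, 2L, apply(xyz, 2L, min)) / radius)
  key <- paste(cell[, 1L], cell[, 2L], cell[, 3L], sep = ",")
  bucket <- split(seq_len(n), key)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  r2 <- radius^2
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ks <- paste(cell[i, 1L] + off[, 1L], cell[i, 2L] + off[, 2L],
                cell[i, 3L] + off[, 3L], sep = ",")
    cand <- unlist(bucket[intersect(ks, names(bucket))], use.names = FALSE)
    d2 <- (xyz[cand, 1L] - xyz[i, 1L])^2 + (xyz[cand, 2L] - xyz[i, 2L])^2 +
      (xyz[cand, 3L] - xyz[i, 3L])^2
    out[[i]] <- cand[d2 <= r2 & cand != i]
  }
  out
}

#' Build spatial neighbour contexts
#'
#' For every atom, finds all atoms within \code{radius} excluding atoms of
#' the center's own residue, and summarizes the environment by the exact
#' median of the neighbours' B values.  Atoms with fewer than
#' \code{min_neighbors} neighbours (e.g. isolated waters at a model's edge)
#' yield no context.
#'
#' @param model a \code{structure_model}.
#' @param radius neighbour search radius in Angstrom; the default 4.2
#'   covers coordination and close-contact distances.
#' @param min_neighbors minimum environment size for a context to be
#'   emitted.
#' @return data frame with one row per retained atom: \code{atom_idx}
#'   (row in \code{model$atoms}), identity columns, \code{b_atom},
#'   \code{n_neighbors}, \code{b_env_median}.  The per-atom neighbour index
#'   lists (for all atoms) are attached as attribute \code{"neighbors"}.
#' @export
build_contexts <- function(model, radius = 4.2, min_neighbors = 4) {
  stopifnot(inherits(model, "structure_model"), radius > 0)
  at <- model$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  nb <- neighbor_lists(xyz, radius)
  res <- residue_key(at)
  nb <- lapply(seq_along(nb), function(i) {
    j <- nb[[i]]
    j[res[j] != res[i]]
  })
  n_nb <- lengths(nb)
  keep <- which(n_nb >= min_neighbors)
  ctx <- data.frame(
    atom_idx = keep,
    chain_id = at$chain_id[keep],
    residue_name = at$residue_name[keep],
    residue_seq = at$residue_seq[keep],
    atom_name = at$atom_name[keep],
    element = at$element[keep],
    b_atom = at$b_iso[keep],
    occupancy = at$occupancy[keep],
    n_neighbors = n_nb[keep],
    b_env_median = vapply(keep, function(i) stats::median(at$b_iso[nb[[i]]]),
                          numeric(1)),
    stringsAsFactors = FALSE)
  attr(ctx, "neighbors") <- nb
  ctx
}

#' Scan all atoms for ADP outliers relative to their environment
#'
#' Computes both relative-occupancy estimates for every atom with a valid
#' neighbour context (\code{b_atom} = the atom's B, \code{b_ref} = the
#' environment median) and flags atoms as \code{"lighter"} when
#' \code{c_total <= light_cut} or \code{"heavier"} when
#' \code{c_total >= heavy_cut}.  Output is sorted by
#' \code{|log c_total|} descending, so the strongest outliers come first.
#'
#' @inheritParams build_contexts
#' @param light_cut flag threshold below 1 (default 0.7).
#' @param heavy_cut flag threshold above 1 (default 1.3).
#' @return data frame of occupancy estimates with columns of
#'   \code{\link{build_contexts}} plus \code{c_total}, \code{c_peak},
#'   \code{flag}.
#' @examples
#' \donttest{
#' toy <- build_toy_structure(tempfile(fileext = ".pdb"),
#'   mixture = sigd_mixture(1, 4, 60, 10), n_per_domain = 343,
#'   d_max = 1.8, anomalies = "heavy", seed = 7)
#' scan <- scan_atoms(read_structure(toy$path))
#' head(scan, 3)
#' }
#' @export
scan_atoms <- function(model, radius = 4.2, min_neighbors = 4,
                       light_cut = 0.7, heavy_cut = 1.3) {
  stopifnot(light_cut < 1, heavy_cut > 1)
  ctx <- build_contexts(model, radius, min_neighbors)
  attr(ctx, "neighbors") <- NULL
  ctx$c_total <- occ_total(ctx$b_atom, ctx$b_env_median, model$s_max)
  ctx$c_peak <- occ_peak(ctx$b_atom, ctx$b_env_median, model$s_max)
  ctx$flag <- ifelse(ctx$c_total <= light_cut, "lighter",
                     ifelse(ctx$c_total >= heavy_cut, "heavier", "ok"))
  ctx <- ctx[order(-abs(log(pmax(ctx$c_total, 1e-300)))), , drop = FALSE]
  rownames(ctx) <- NULL
  ctx
}

water_names <- c("HOH", "WAT", "DOD")

#' Ligand relative-occupancy report
#'
#' Compares the median ADP of a ligand's atoms with the median ADP of its
#' spatial environment — all non-ligand, non-water atoms within
#' \code{radius} of any ligand atom — and converts the difference into
#' relative occupancies at the model's resolution.  Waters are excluded
#' from the environment because they are freely re-placed during
#' rebuilding and would bias the median.
#'
#' @param model a \code{structure_model}.
#' @param resname 3-letter residue name of the ligand.
#' @param chain optional chain id restricting the selection.
#' @param seq optional residue number restricting the selection.
#' @param radius environment radius in Angstrom (default 4.2).
#' @return one-row data frame of class \code{ligand_report}:
#'   \code{resname}, \code{chain}, \code{seq}, \code{n_ligand_atoms},
#'   \code{n_env_atoms}, \code{median_b_ligand}, \code{median_b_env},
#'   \code{c_total}, \code{c_peak}.
#' @export
ligand_report <- function(model, resname, chain = NULL, seq = NULL,
                          radius = 4.2) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  sel <- at$residue_name == resname
  if (!is.null(chain)) sel <- sel & at$chain_id == chain
  if (!is.null(seq)) sel <- sel & at$residue_seq == seq
  if (!any(sel)) stop("ligand selector matches no atoms: ", resname)
  lig <- which(sel)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  cand <- which(!sel & !(at$residue_name %in% water_names))
  if (!length(cand)) stop("empty environment for ligand ", resname)
  r2 <- radius^2
  near <- vapply(cand, function(j) {
    any((xyz[lig, 1L] - xyz[j, 1L])^2 + (xyz[lig, 2L] - xyz[j, 2L])^2 +
          (xyz[lig, 3L] - xyz[j, 3L])^2 <= r2)
  }, logical(1))
  env <- cand[near]
  if (!length(env)) stop("empty environment for ligand ", resname)
  mb_lig <- stats::median(at$b_iso[lig])
  mb_env <- stats::median(at$b_iso[env])
  out <- data.frame(
    resname = resname,
    chain = if (is.null(chain)) paste(unique(at$chain_id[lig]),
                                      collapse = ",") else chain,
    seq = if (is.null(seq)) paste(unique(at$residue_seq[lig]),
                                  collapse = ",") else as.character(seq),
    n_ligand_atoms = length(lig),
    n_env_atoms = length(env),
    median_b_ligand = mb_lig,
    median_b_env = mb_env,
    c_total = occ_total(mb_lig, mb_env, model$s_max),
    c_peak = occ_peak(mb_lig, mb_env, model$s_max),
    stringsAsFactors = FALSE)
  class(out) <- c("ligand_report", class(out))
  out
}
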
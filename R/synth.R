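#' Sample B values from a SIGD mixture
#'
#' Forward simulation of the mixture law: each value's component is drawn
#' from the mixture weights, the value itself from that component's shifted
#' inverse-gamma distribution (\code{B = B0 + beta / G}, \code{G} a standard
#' gamma draw).  True component labels are returned for recovery tests.
#'
#' @param mixture a \code{\link{sigd_mixture}} (the ground truth).
#' @param n number of values.
#' @param seed integer seed; the draw is fully reproducible.
#' @return list with \code{b} (values, \eqn{\mathrm{\AA}^2}) and
#'   \code{labels} (1-based component indices, in the mixture's sorted
#'   order).
#' @examples
#' mx <- sigd_mixture(c(0.6, 0.4), c(4, 8), c(60, 400), c(5, 40))
#' sim <- sample_mixture(mx, 1000, seed = 1)
#' table(sim$labels)
#' @export
sample_mixture <- function(mixture, n, seed = 0) {
  stopifnot(inherits(mixture, "sigd_mixture"), n >= 0)
  set.seed(seed)
  if (n == 0L) return(list(b = numeric(0), labels = integer(0)))
  k <- sample.int(mixture$n_modes, n, replace = TRUE,
                  prob = mixture$weights)
  b <- numeric(n)
  for (j in seq_len(mixture$n_modes)) {
    idx <- which(k == j)
    if (length(idx)) {
      cc <- mixture$components[[j]]
      b[idx] <- cc$b0 + cc$beta / stats::rgamma(length(idx),
                                                shape = cc$alpha)
    }
  }
  list(b = b, labels = k)
}

# Jittered cubic lattice of >= n points, centred near the origin.
lattice_block <- function(n, spacing = 1.8, jitter = 0.15) {
  m <- ceiling(n^(1 / 3))
  g <- expand.grid(i = seq_len(m), j = seq_len(m), k = seq_len(m))
  g <- g[seq_len(n), , drop = FALSE]
  xyz <- as.matrix(g) * spacing
  xyz + matrix(stats::runif(3 * n, -jitter, jitter), ncol = 3)
}

#' Build a synthetic coordinate file with known ground truth
#'
#' Generates a minimal, valid PDB file whose B values follow a known SIGD
#' mixture, so the global and local analyses can be exercised without any
#' real structure.  Atoms sit on a jittered cubic lattice (spacing 1.8
#' Angstrom, jitter 0.15) partitioned into spatially contiguous blocks, one
#' block per mixture component — mirroring real multimodal structures where
#' modes correspond to spatial domains — and each atom is its own one-atom
#' residue so that neighbour environments exclude only the atom itself.
#' The header carries the resolution limit, so the file round-trips through
#' \code{\link{read_structure}}.
#'
#' Planted anomalies (all with recorded ground truth):
#' \describe{
#'   \item{\code{"heavy"}}{one interior O atom is given B = half its
#'     environment median — a metal modelled as a water.}
#'   \item{\code{"light"}}{one interior atom gets B = twice its environment
#'     median — a misplaced/partial atom.}
#'   \item{\code{"half_ligand"}}{a contiguous 8-atom block is relabelled as
#'     a hetero ligand \code{LIG} whose uniform B is chosen (by numerically
#'     inverting \code{\link{occ_total}}) so that its total-density relative
#'     occupancy is \code{target_occ}.}
#'   \item{\code{"octahedron"}}{an O atom with six O neighbours at 2.1
#'     Angstrom forming a regular octahedron, B = half the environment
#'     median — the classic misassigned-metal coordination site.}
#' }
#'
#' @param path output PDB path.
#' @param mixture a \code{\link{sigd_mixture}} ground truth.
#' @param n_per_domain atoms per spatial domain (recycled over components).
#' @param d_max resolution limit written to the header, Angstrom.
#' @param anomalies character vector from
#'   \code{c("heavy", "light", "half_ligand", "octahedron")}.
#' @param target_occ construction value for the half-density ligand
#'   (default 0.5).
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   output.
#' @return list with \code{path}, \code{truth}: \code{labels} (generating
#'   component per atom, in file order), \code{domain_of_atom},
#'   \code{anomaly_idx} (named list of planted atom indices),
#'   \code{ligand_b}, \code{target_occ}, \code{d_max}.
#' @export
build_toy_structure <- function(path, mixture, n_per_domain = 500,
                                d_max = 2.0, anomalies = character(0),
                                target_occ = 0.5, seed = 0) {
  stopifnot(inherits(mixture, "sigd_mixture"), d_max > 0)
  if (length(anomalies))
    anomalies <- match.arg(anomalies,
                           c("heavy", "light", "half_ligand", "octahedron"),
                           several.ok = TRUE)
  set.seed(seed)
  k <- mixture$n_modes
  npd <- rep_len(n_per_domain, k)
  xyz <- NULL; labels <- integer(0)
  xoff <- 0
  for (j in seq_len(k)) {
    blk <- lattice_block(npd[j])
    blk[, 1L] <- blk[, 1L] + xoff
    xoff <- max(blk[, 1L]) + 6   # gap so domains do not touch
    xyz <- rbind(xyz, blk)
    labels <- c(labels, rep.int(j, npd[j]))
  }
  n <- nrow(xyz)
  b <- numeric(n)
  for (j in seq_len(k)) {
    cc <- mixture$components[[j]]
    idx <- which(labels == j)
    b[idx] <- cc$b0 + cc$beta / stats::rgamma(length(idx), shape = cc$alpha)
  }
  # one-atom GLY "residues" so neighbour environments exclude only self;
  # non-water so they count as ligand environment
  atoms <- data.frame(
    chain_id = "A",
    residue_name = "GLY",
    residue_seq = seq_len(n),
    insertion_code = "",
    atom_name = "CA",
    alt_loc = "",
    element = "C",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    b_iso = b,
    occupancy = 1,
    is_hetero = FALSE,
    stringsAsFactors = FALSE)

  s_max <- 1 / d_max
  anomaly_idx <- list()
  ligand_b <- NA_real_

  env_median <- function(i, exclude = integer(0)) {
    d2 <- (atoms$x - atoms$x[i])^2 + (atoms$y - atoms$y[i])^2 +
      (atoms$z - atoms$z[i])^2
    j <- which(d2 <= 4.2^2 & d2 > 0)
    j <- setdiff(j, exclude)
    stats::median(atoms$b_iso[j])
  }
  # deterministic "interior" picks: atoms nearest the domain-1 centroid
  centroid_order <- function(exclude = integer(0)) {
    d1 <- which(labels == 1L)
    cx <- colMeans(xyz[d1, , drop = FALSE])
    d2 <- (atoms$x - cx[1L])^2 + (atoms$y - cx[2L])^2 + (atoms$z - cx[3L])^2
    setdiff(order(d2), exclude)
  }

  used <- integer(0)
  if ("heavy" %in% anomalies) {
    i <- centroid_order(used)[1L]
    atoms$b_iso[i] <- env_median(i) / 2
    # a metal modelled as a water: water record with a too-low B
    atoms$residue_name[i] <- "HOH"
    atoms$atom_name[i] <- "O"
    atoms$element[i] <- "O"
    atoms$is_hetero[i] <- TRUE
    anomaly_idx$heavy <- i
    used <- c(used, i)
  }
  if ("light" %in% anomalies) {
    i <- centroid_order(used)[1L]
    atoms$b_iso[i] <- env_median(i) * 2
    anomaly_idx$light <- i
    used <- c(used, i)
  }
  if ("half_ligand" %in% anomalies) {
    i <- centroid_order(used)[1L]
    d2 <- (atoms$x - atoms$x[i])^2 + (atoms$y - atoms$y[i])^2 +
      (atoms$z - atoms$z[i])^2
    lig <- setdiff(order(d2), used)[1:8]
    atoms$residue_name[lig] <- "LIG"
    atoms$residue_seq[lig] <- max(atoms$residue_seq) + 1L
    atoms$atom_name[lig] <- paste0("C", seq_along(lig))
    atoms$is_hetero[lig] <- TRUE
    # environment exactly as ligand_report sees it: non-ligand, non-water
    # atoms within 4.2 A of any ligand atom
    env <- which(!(seq_len(nrow(atoms)) %in% lig) &
                   !(atoms$residue_name %in% water_names))
    keep <- vapply(env, function(j) {
      any((atoms$x[lig] - atoms$x[j])^2 + (atoms$y[lig] - atoms$y[j])^2 +
            (atoms$z[lig] - atoms$z[j])^2 <= 4.2^2)
    }, logical(1))
    env_b <- stats::median(round(atoms$b_iso[env[keep]], 2))
    # invert occ_total in b_atom: find B with occ_total(B, env_b) = target
    ligand_b <- round(stats::uniroot(
      function(bb) occ_total(bb, env_b, s_max) - target_occ,
      lower = 0, upper = 1e5, tol = 1e-10)$root, 2)
    atoms$b_iso[lig] <- ligand_b
    anomaly_idx$half_ligand <- lig
    used <- c(used, lig)
  }
  if ("octahedron" %in% anomalies) {
    ctr <- c(-12, 0, 0)   # clear of every lattice domain
    oct <- rbind(c(2.1, 0, 0), c(-2.1, 0, 0), c(0, 2.1, 0),
                 c(0, -2.1, 0), c(0, 0, 2.1), c(0, 0, -2.1))
    env_b <- stats::median(atoms$b_iso[labels == 1L])
    new <- data.frame(
      chain_id = "A", residue_name = "HOH",
      residue_seq = max(atoms$residue_seq) + seq_len(7L),
      insertion_code = "", atom_name = "O", alt_loc = "", element = "O",
      x = ctr[1L] + c(0, oct[, 1L]), y = ctr[2L] + c(0, oct[, 2L]),
      z = ctr[3L] + c(0, oct[, 3L]),
      b_iso = c(env_b / 2, rep(env_b, 6L)),
      occupancy = 1, is_hetero = TRUE, stringsAsFactors = FALSE)
    anomaly_idx$octahedron <- nrow(atoms) + 1L
    atoms <- rbind(atoms, new)
    labels <- c(labels, rep.int(NA_integer_, 7L))
  }

  write_model_pdb(atoms, round(atoms$b_iso, 2), d_max, path)
  list(path = path,
       truth = list(labels = labels, domain_of_atom = labels,
                    anomaly_idx = anomaly_idx, ligand_b = ligand_b,
                    target_occ = target_occ, d_max = d_max,
                    mixture = mixture))
}
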
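#' Simulation parameters for the hexagonal-lattice clonal dynamics model
#'
#' Bundles every rate and geometry constant of the lattice model. Stem-cell
#' loss/replacement is the classic voter-model move: a stem cell is lost (to
#' differentiation) and the vacancy is filled by the division of a uniformly
#' chosen occupied stem neighbour, all within one daily time step.
#'
#' Units follow the biology literature: `lam` and `phi` are per cell per
#' *week* (the basal-layer loss/replacement rate is estimated at 0.5/week);
#' all other rates are per cell per *day*. Weekly rates are converted to daily
#' probabilities as rate/7 * `dt`, valid because `lam * dt / 7` is well below 1.
#'
#' @param width,height Lattice dimensions in sites. With the default toroidal
#'   boundary `height` must be even so hex row parity is consistent across the
#'   wrap seam.
#' @param lam Wild-type stem loss/replacement rate, per cell per week.
#' @param phi Mutant (B-cell) loss rate, per cell per week; `phi < lam`
#'   encodes a competitive advantage (reduced exit from the stem compartment).
#' @param omega Neutral mutation rate, per cell per day.
#' @param theta Non-neutral (advantaged) mutation rate, per cell per day.
#' @param kappa Migration swap rate per adjacent cell pair per day. The
#'   physical estimate of 10 um/day with a 10 um cell diameter corresponds to
#'   about one swap attempt per cell pair per day (`kappa = 1`).
#' @param nu Stem-to-TA differentiation rate, per cell per day, applied where
#'   the differentiation map is 1.
#' @param q_max Maximum number of divisions a transit-amplifying cell may
#'   complete.
#' @param ta_div_rate,ta_loss_rate TA division and loss rates per cell per
#'   day. Defaults: TA cells compete for vacancies at the stem replacement
#'   rate (`lam/7`), and turn over after about `q_max` divisions.
#' @param cluster_radius,cluster_spacing Stem-cluster geometry in cells for
#'   the heterogeneous compartment (see [make_diff_map()]).
#' @param penalty_p Scalar penalty in the lattice-energy function; large
#'   values confine stem cells to clusters and TA cells outside them.
#' @param dt Time step in days (the model is quantised at 1 day).
#' @param duration Simulated time in days.
#' @param boundary `"torus"` (default; avoids edge artefacts on clone growth)
#'   or `"clip"` for a non-wrapping edge.
#' @param detect_vaf Variant allele fraction below which a clone is considered
#'   undetectable by sequencing (default 0.007).
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(width, height, lam = 0.5, phi = lam, omega = 1e-3,
                       theta = 0, kappa = 0, nu = 0, q_max = 4,
                       ta_div_rate = lam / 7, ta_loss_rate = ta_div_rate / q_max,
                       cluster_radius = 20, cluster_spacing = 3 * cluster_radius,
                       penalty_p = 100, dt = 1, duration = 365,
                       boundary = c("torus", "clip"), detect_vaf = 0.007) {
  boundary <- match.arg(boundary)
  stopifnot(width >= 1, height >= 1)
  rates <- c(lam = lam, phi = phi, omega = omega, theta = theta, kappa = kappa,
             nu = nu, ta_div_rate = ta_div_rate, ta_loss_rate = ta_loss_rate)
  if (any(rates < 0)) abort("all rates must be non-negative")
  if (boundary == "torus" && height %% 2 != 0)
    abort("toroidal boundary requires an even number of rows (hex row parity)")
  structure(list(
    width = as.integer(width), height = as.integer(height),
    lam = lam, phi = phi, omega = omega, theta = theta, kappa = kappa,
    nu = nu, q_max = as.integer(q_max),
    ta_div_rate = ta_div_rate, ta_loss_rate = ta_loss_rate,
    cluster_radius = cluster_radius, cluster_spacing = cluster_spacing,
    penalty_p = penalty_p, dt = dt, duration = as.integer(duration),
    boundary = boundary, detect_vaf = detect_vaf
  ), class = "sim_params")
}

daily_probs <- function(p) {
  list(
    torus = p$boundary == "torus",
    p_loss_a = p$lam * p$dt / 7,
    p_loss_b = p$phi * p$dt / 7,
    p_mut = p$omega * p$dt,
    p_nn = p$theta * p$dt,
    p_swap = p$kappa * p$dt,
    p_diff = p$nu * p$dt,
    p_tadiv = p$ta_div_rate * p$dt,
    p_taloss = p$ta_loss_rate * p$dt,
    q_max = p$q_max,
    penalty = p$penalty_p
  )
}

#' Hexagonal neighbourhood of a lattice site
#'
#' Sites use odd-row offset coordinates on a rectangular array: odd rows are
#' shifted half a cell to the right, so each interior site has exactly six
#' neighbours. With the toroidal boundary every site has six; with `"clip"`
#' edge and corner sites have fewer.
#'
#' @param site Integer vector `c(row, col)`, 1-based.
#' @param dims Integer vector `c(height, width)`.
#' @param boundary `"torus"` or `"clip"`.
#' @return An integer matrix with columns `row`, `col`, one neighbour per row.
#' @export
hex_neighbors <- function(site, dims, boundary = c("torus", "clip")) {
  boundary <- match.arg(boundary)
  if (length(site) != 2 || length(dims) != 2) abort("site and dims must have length 2")
  if (site[1] < 1 || site[1] > dims[1] || site[2] < 1 || site[2] > dims[2])
    abort("site out of range")
  m <- cpp_neighbors(as.integer(site[1]) - 1L, as.integer(site[2]) - 1L,
                     as.integer(dims[1]), as.integer(dims[2]),
                     boundary == "torus")
  m <- m + 1L
  colnames(m) <- c("row", "col")
  m
}

#' Differentiation map with circular stem-cell clusters
#'
#' Builds the binary map diff(i) for the heterogeneous compartment: 0 inside
#' circular stem clusters (no differentiation), 1 outside. Cluster centres sit
#' on a regular triangular grid with the given spacing; distances use the
#' physical coordinates of the odd-row offset layout (odd rows shifted by half
#' a cell, rows sqrt(3)/2 apart).
#'
#' @param width,height Lattice dimensions in sites.
#' @param cluster_radius Cluster radius in cells.
#' @param cluster_spacing Distance between neighbouring cluster centres, cells.
#' @return An integer matrix (`height` x `width`) of 0/1.
#' @export
make_diff_map <- function(width, height, cluster_radius = 20,
                          cluster_spacing = 3 * cluster_radius) {
  rows <- seq_len(height)
  cols <- seq_len(width)
  x <- outer(rep(1, height), cols) + 0.5 * ((rows - 1) %% 2)
  y <- matrix(rep((rows - 1) * sqrt(3) / 2, width), nrow = height)
  row_step <- cluster_spacing * sqrt(3) / 2
  centre_rows <- seq(row_step / 2, height * sqrt(3) / 2, by = row_step)
  dmap <- matrix(1L, height, width)
  for (i in seq_along(centre_rows)) {
    offset <- if (i %% 2 == 0) cluster_spacing / 2 else 0
    centre_cols <- seq(cluster_spacing / 2 + offset, width + cluster_spacing,
                       by = cluster_spacing)
    for (cx in centre_cols) {
      inside <- (x - cx)^2 + (y - centre_rows[i])^2 <= cluster_radius^2
      dmap[inside] <- 0L
    }
  }
  dmap
}

new_tree <- function(live0) {
  tibble(label = 0L, parent = NA_integer_, birth_day = 0L,
         class = "root", live = as.numeric(live0), active = TRUE)
}

#' Initialise a lattice state
#'
#' Homogeneous mode starts fully occupied by wild-type stem cells with clonal
#' identity 0 (the root clone). Heterogeneous mode places stem cells inside
#' the clusters of `diff_map`, TA cells (q = 0) outside, and converts a
#' fraction `init_empty_frac` of non-cluster sites to vacancies.
#'
#' @param params A [sim_params()] object.
#' @param mode `"homogeneous"` or `"heterogeneous"`.
#' @param diff_map Binary differentiation map (required for heterogeneous
#'   mode; built with [make_diff_map()] if `NULL`).
#' @param init_empty_frac Initial vacancy fraction outside clusters
#'   (heterogeneous mode only).
#' @return A list of class `lattice_state` with matrices `kind` (0 empty, 1
#'   stem A, 2 mutant stem B, 3 TA), `label`, `q`, the clone `tree` tibble and
#'   elapsed `time` in days.
#' @export
lattice_init <- function(params, mode = c("homogeneous", "heterogeneous"),
                         diff_map = NULL, init_empty_frac = 0.05) {
  mode <- match.arg(mode)
  H <- params$height; W <- params$width
  kind <- matrix(1L, H, W)
  label <- matrix(0L, H, W)
  q <- matrix(0L, H, W)
  if (mode == "heterogeneous") {
    if (is.null(diff_map)) {
      if (params$cluster_radius >= min(W, H) / 2)
        abort("cluster_radius must be smaller than half the lattice extent")
      diff_map <- make_diff_map(W, H, params$cluster_radius, params$cluster_spacing)
    }
    stopifnot(all(dim(diff_map) == c(H, W)))
    kind[diff_map == 1L] <- 3L
    outside <- which(diff_map == 1L)
    if (init_empty_frac > 0 && length(outside) > 0) {
      n_empty <- round(init_empty_frac * length(outside))
      holes <- sample(outside, n_empty)
      kind[holes] <- 0L
      label[holes] <- -1L
    }
  }
  structure(list(kind = kind, label = label, q = q,
                 tree = new_tree(sum(kind != 0L)), time = 0L,
                 mode = mode, diff_map = diff_map),
            class = "lattice_state")
}

tree_to_cpp <- function(tree) {
  list(parent = ifelse(is.na(tree$parent), -1L, tree$parent),
       birth = tree$birth_day,
       class = match(tree$class, c("root", "neutral", "non_neutral")) - 1L,
       live = tree$live,
       active = tree$active)
}

cpp_to_tree <- function(res) {
  tibble(label = seq_along(res$tree_parent) - 1L,
         parent = ifelse(res$tree_parent < 0, NA_integer_, res$tree_parent),
         birth_day = res$tree_birth,
         class = c("root", "neutral", "non_neutral")[res$tree_class + 1L],
         live = res$tree_live,
         active = res$tree_active)
}

#' Advance a lattice state by whole days
#'
#' Executes the daily update cycle: simultaneous stem losses, vacancy filling
#' by uniformly chosen stem neighbours, neutral and non-neutral mutations,
#' the TA compartment (heterogeneous mode), then migration (energy-gated in
#' heterogeneous mode). All transitions initiate and complete within one step.
#'
#' @param state A `lattice_state`.
#' @param params A [sim_params()] object.
#' @param n_days Number of days to advance.
#' @param purge_every Purge cadence in days for extinct clone records
#'   (0 disables purging).
#' @return The updated `lattice_state`.
#' @export
lattice_step <- function(state, params, n_days = 1, purge_every = 30) {
  stopifnot(inherits(state, "lattice_state"))
  tr <- tree_to_cpp(state$tree)
  res <- cpp_sim_run(state$kind, state$label, state$q,
                     tr$parent, tr$birth, tr$class, tr$live, tr$active,
                     daily_probs(params), state$mode == "heterogeneous",
                     state$diff_map, as.integer(state$time),
                     as.integer(n_days), integer(0), as.integer(purge_every))
  state$kind <- res$kind; state$label <- res$label; state$q <- res$q
  state$tree <- cpp_to_tree(res)
  state$time <- res$end_day
  state
}

#' Migration sweep over the lattice
#'
#' Attempts one stochastic content swap per adjacent site pair with
#' probability `kappa * dt`. In heterogeneous (energy-gated) mode a proposed
#' swap is applied only if it strictly reduces the total lattice energy.
#'
#' @inheritParams lattice_step
#' @param gated Apply the lattice-energy gate (`TRUE` for the heterogeneous
#'   compartment). Defaults to the state's mode.
#' @return The updated `lattice_state`.
#' @export
lattice_migrate <- function(state, params, gated = NULL) {
  stopifnot(inherits(state, "lattice_state"))
  gated <- gated %||% (state$mode == "heterogeneous")
  res <- cpp_migrate(state$kind, state$label, state$q,
                     params$kappa * params$dt, gated, state$diff_map,
                     params$penalty_p, params$boundary == "torus")
  state$kind <- res$kind; state$label <- res$label; state$q <- res$q
  state
}

#' Lattice energy of a single occupied site
#'
#' For a stem occupant the energy is the number of TA neighbours plus
#' `diff(i) * p`; for a TA occupant it is the number of stem neighbours minus
#' the number of empty neighbours plus `(1 - diff(i)) * p`. Mutant stem cells
#' (B) count as stem. High energy marks stem cells admixed with TA cells or
#' TA cells sitting inside a stem cluster.
#'
#' @param state A `lattice_state`.
#' @param site `c(row, col)`, 1-based; must be occupied.
#' @param diff_map Binary differentiation map (defaults to the state's map, or
#'   all-zero if none).
#' @param penalty_p Scalar penalty `p`.
#' @param boundary Boundary rule used for the neighbourhood.
#' @return The energy value (numeric scalar).
#' @export
lattice_energy <- function(state, site, diff_map = NULL, penalty_p = 100,
                           boundary = "torus") {
  kind <- state$kind
  k <- kind[site[1], site[2]]
  if (k == 0L) abort("energy is undefined for an empty site")
  diff_map <- diff_map %||% state$diff_map
  d <- if (is.null(diff_map)) 0 else diff_map[site[1], site[2]]
  nb <- hex_neighbors(site, dim(kind), boundary)
  kk <- kind[cbind(nb[, 1], nb[, 2])]
  if (k %in% c(1L, 2L)) {
    sum(kk == 3L) + d * penalty_p
  } else {
    sum(kk %in% c(1L, 2L)) - sum(kk == 0L) + (1 - d) * penalty_p
  }
}

#' Total lattice energy
#'
#' Sum of [lattice_energy()] over all occupied sites; the quantity that the
#' energy-gated migration rule never increases.
#'
#' @inheritParams lattice_energy
#' @export
total_lattice_energy <- function(state, diff_map = NULL, penalty_p = 100,
                                 boundary = "torus") {
  diff_map <- diff_map %||% state$diff_map
  cpp_total_energy(state$kind, diff_map, penalty_p, boundary == "torus")
}

#' Run a lattice simulation
#'
#' Initialises a lattice (unless `state` is supplied) and advances it for
#' `params$duration` days, recording recursive clone sizes at the requested
#' checkpoints. Extinct clone records are purged periodically; purging is
#' observationally silent for surviving clones.
#'
#' @inheritParams lattice_init
#' @param checkpoints Integer days at which to record clone sizes (default:
#'   the final day only).
#' @param seed RNG seed; the full trajectory is reproducible given the seed.
#' @param state Optional starting `lattice_state`.
#' @inheritParams lattice_step
#' @return A list of class `lattice_sim` with elements `clones` (tibble:
#'   `day`, `label`, `parent`, `class`, `birth_day`, `cells`, `vaf`), `state`,
#'   `tree`, `params`, `mode`.
#' @export
run_lattice <- function(params, mode = c("homogeneous", "heterogeneous"),
                        diff_map = NULL, checkpoints = NULL, seed = NULL,
                        state = NULL, purge_every = 30,
                        init_empty_frac = 0.05) {
  mode <- match.arg(mode)
  if (params$duration <= 0) abort("duration must be positive; use lattice_init() for day 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) state <- lattice_init(params, mode, diff_map, init_empty_frac)
  checkpoints <- as.integer(checkpoints %||% params$duration)
  tr <- tree_to_cpp(state$tree)
  res <- cpp_sim_run(state$kind, state$label, state$q,
                     tr$parent, tr$birth, tr$class, tr$live, tr$active,
                     daily_probs(params), state$mode == "heterogeneous",
                     state$diff_map, as.integer(state$time),
                     as.integer(params$duration), checkpoints,
                     as.integer(purge_every))
  state$kind <- res$kind; state$label <- res$label; state$q <- res$q
  state$tree <- cpp_to_tree(res)
  state$time <- res$end_day
  total <- sum(state$kind != 0L)
  clones <- tibble(
    day = res$cp_day, label = res$cp_label, parent = res$cp_parent,
    class = c("root", "neutral", "non_neutral")[res$cp_class + 1L],
    birth_day = res$cp_birth, cells = res$cp_cells
  )
  clones$vaf <- clones$cells / total / 2
  structure(list(clones = clones, state = state, tree = state$tree,
                 params = params, mode = mode, total_cells = total),
            class = "lattice_sim")
}

#' Recursive clone sizes of a lattice state
#'
#' The size of clone n is the recursive sum of its own live cells and the
#' sizes of all descendant clones: a cell contributes to its own clone and to
#' every ancestor clone. VAFs use the heterozygous diploid convention,
#' VAF = cell fraction / 2.
#'
#' @param x A `lattice_sim` or `lattice_state`.
#' @param label Optional single clone label; returns just that clone's row.
#' @param min_vaf If set, keep only clones with VAF above this detection
#'   threshold.
#' @return A tibble of class `clone_size_sample` with columns `label`,
#'   `parent`, `class`, `cells`, `vaf`, and attributes `total_cells` and
#'   `detect_vaf`.
#' @export
clone_sizes <- function(x, label = NULL, min_vaf = NULL) {
  state <- if (inherits(x, "lattice_sim")) x$state else x
  stopifnot(inherits(state, "lattice_state"))
  tree <- state$tree
  live <- tabulate(state$label + 1L, nbins = nrow(tree))
  rec <- cpp_recursive_sizes(ifelse(is.na(tree$parent), -1L, tree$parent),
                             as.numeric(live))
  total <- sum(state$kind != 0L)
  out <- tibble(label = tree$label, parent = tree$parent, class = tree$class,
                cells = rec, vaf = rec / total / 2)
  if (!is.null(label)) {
    if (!label %in% out$label) abort(sprintf("unknown clone label %s", label))
    out <- out[out$label == label, ]
  } else {
    out <- out[out$cells > 0 & tree$active, ]
  }
  if (!is.null(min_vaf)) out <- out[out$vaf > min_vaf, ]
  structure(out, class = c("clone_size_sample", class(out)),
            total_cells = total, detect_vaf = min_vaf)
}

#' @export
print.lattice_sim <- function(x, ...) {
  cat(sprintf("<lattice_sim> %dx%d %s, %d days, %d live clones\n",
              x$params$height, x$params$width, x$mode, x$state$time,
              sum(x$tree$active & x$tree$live > 0)))
  invisible(x)
}
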
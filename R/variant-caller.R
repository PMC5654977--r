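#' Beta-binomial log likelihood
#'
#' Log probability mass of `x` successes in `n` trials under a beta-binomial
#' with mean `mu` and overdispersion `rho` (the intraclass correlation).
#' Shape parameters: `alpha = mu * (1 - rho) / rho`,
#' `beta = (1 - mu) * (1 - rho) / rho`; as `rho -> 0` the distribution
#' converges to the binomial. `mu = 0` (or 1) is treated as a point mass.
#'
#' @param x Observed counts (0 <= x <= n), vectorised.
#' @param n Trial counts (coverage).
#' @param mu Mean fraction in \[0, 1\].
#' @param rho Overdispersion in (0, 1).
#' @return Log likelihoods, same length as the longest argument.
#' @export
betabin_loglik <- function(x, n, mu, rho) {
  if (any(x > n)) abort("x must not exceed n")
  if (any(x < 0) || any(n < 0)) abort("counts must be non-negative")
  if (any(rho <= 0) || any(rho >= 1)) abort("rho must be in (0, 1)")
  k <- max(length(x), length(n), length(mu), length(rho))
  x <- rep_len(x, k); n <- rep_len(n, k)
  mu <- rep_len(mu, k); rho <- rep_len(rho, k)
  out <- numeric(k)
  deg0 <- mu <= 0
  deg1 <- mu >= 1
  out[deg0] <- ifelse(x[deg0] == 0, 0, -Inf)
  out[deg1] <- ifelse(x[deg1] == n[deg1], 0, -Inf)
  ok <- !deg0 & !deg1
  if (any(ok)) {
    a <- mu[ok] * (1 - rho[ok]) / rho[ok]
    b <- (1 - mu[ok]) * (1 - rho[ok]) / rho[ok]
    out[ok] <- lchoose(n[ok], x[ok]) +
      lbeta(x[ok] + a, n[ok] - x[ok] + b) - lbeta(a, b)
  }
  out
}

#' Fit the strand-specific background error model from control samples
#'
#' Per site, per alternate allele and per strand, the mean error fraction is
#' the pooled count fraction across all control samples (pooled rather than
#' averaged per-sample fractions, which weights deeper samples more; set
#' `per_sample_mean = TRUE` for the unweighted mean). A single overdispersion
#' `rho` is then estimated across all captured sites jointly by profile
#' likelihood over a log-spaced grid in \[1e-6, 0.5\] followed by local
#' refinement.
#'
#' @param control_counts Count table in long format with columns `sample`,
#'   `chrom`, `pos`, `ref`, `strand` ("fwd"/"rev"), `A`, `C`, `G`, `T`, `DEL`,
#'   `depth`. At least two control samples are required.
#' @param per_sample_mean Use the mean of per-sample fractions instead of the
#'   pooled fraction.
#' @param rho_bounds Search interval for `rho`.
#' @param grid_n Number of grid points for the profile-likelihood scan.
#' @return An object of class `error_model`: tibble `v` (chrom, pos, ref,
#'   strand, allele, v = raw pooled fraction, v_test = fraction floored at
#'   half a read over the pooled depth, used by the LRT, depth_total), scalar
#'   `rho`, and `excluded` (sites with zero coverage on a strand, flagged and
#'   excluded).
#' @export
fit_error_model <- function(control_counts, per_sample_mean = FALSE,
                            rho_bounds = c(1e-6, 0.5), grid_n = 40) {
  check_count_table(control_counts)
  if (dplyr::n_distinct(control_counts$sample) < 2)
    abort("need at least 2 control samples to build the background model")
  long <- counts_to_long(control_counts)
  # pooled (or per-sample-averaged) mean fraction per site/allele/strand
  v_tbl <- long |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$strand, .data$allele) |>
    dplyr::summarise(
      v = if (per_sample_mean) mean(ifelse(.data$depth > 0, .data$count / .data$depth, NA_real_), na.rm = TRUE)
          else sum(.data$count) / sum(.data$depth),
      depth_total = sum(.data$depth), .groups = "drop")
  excluded <- v_tbl |>
    dplyr::filter(.data$depth_total == 0 | is.nan(.data$v)) |>
    dplyr::distinct(.data$chrom, .data$pos, .data$strand)
  v_tbl <- v_tbl |>
    dplyr::anti_join(excluded, by = c("chrom", "pos", "strand"))
  # rate used in testing: a site/strand where the pooled panel saw zero reads
  # is floored at half a read over the pooled depth, so a single stray read
  # in a test sample is not infinitely significant
  v_tbl <- v_tbl |>
    dplyr::mutate(v_test = pmax(.data$v, 0.5 / .data$depth_total))
  # overdispersion: joint profile likelihood over alternate-allele counts
  fit_dat <- long |>
    dplyr::inner_join(v_tbl, by = c("chrom", "pos", "ref", "strand", "allele")) |>
    dplyr::filter(.data$allele != .data$ref, .data$depth > 0, .data$v > 0)
  if (nrow(fit_dat) == 0) {
    # no informative alternate counts at all: no overdispersion measurable
    return(structure(list(v = v_tbl, rho = rho_bounds[1], excluded = excluded,
                          rho_bounds = rho_bounds, loglik = 0),
                     class = "error_model"))
  }
  ll <- function(rho) sum(betabin_loglik(fit_dat$count, fit_dat$depth, fit_dat$v, rho))
  grid <- exp(seq(log(rho_bounds[1]), log(rho_bounds[2]), length.out = grid_n))
  lls <- vapply(grid, ll, numeric(1))
  i <- which.max(lls)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(grid_n, i + 1)]
  opt <- optimize(function(lr) ll(exp(lr)), c(log(lo), log(hi)), maximum = TRUE)
  rho <- exp(opt$maximum)
  structure(list(v = v_tbl, rho = rho, excluded = excluded,
                 rho_bounds = rho_bounds, loglik = opt$objective),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("<error_model> rho = %.3g over %d site/allele/strand rates (%d sites excluded)\n",
              x$rho, nrow(x$v), nrow(x$excluded)))
  invisible(x)
}

#' @method glance error_model
#' @export
glance.error_model <- function(x, ...) {
  tibble(rho = x$rho, n_rates = nrow(x$v), n_excluded = nrow(x$excluded),
         loglik = x$loglik)
}

#' Strand-aware likelihood-ratio test at one site
#'
#' Null model: the forward and reverse counts follow the background
#' beta-binomials with strand-specific means `v`, `vp` and shared `rho`.
#' Alternative: both strands share the mean
#' `mu = (x + xp) / (n + np)` (a genuine variant is present equally on both
#' strands, unlike a strand-biased PCR artefact). The statistic
#' `LR = 2 * (l1 - l0)` (floored at 0) is referred to a chi-squared
#' distribution with 2 degrees of freedom.
#'
#' @param x,xp Alternate counts on the forward / reverse strand.
#' @param n,np Coverage on the forward / reverse strand.
#' @param v,vp Background mean error fractions per strand.
#' @param rho Shared overdispersion.
#' @return P-values (upper chi-squared tail), vectorised.
#' @export
lrt_site <- function(x, xp, n, np, v, vp, rho) {
  if (any(n <= 0) || any(np <= 0)) abort("strand coverages must be positive")
  mu <- (x + xp) / (n + np)
  l0 <- betabin_loglik(x, n, v, rho) + betabin_loglik(xp, np, vp, rho)
  l1 <- betabin_loglik(x, n, mu, rho) + betabin_loglik(xp, np, mu, rho)
  lr <- pmax(0, 2 * (l1 - l0))
  lr[mu == 0] <- 0  # zero alternate reads are never evidence for a variant
  pchisq(lr, df = 2, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false discovery rate correction (via
#' [stats::p.adjust()]).
#'
#' @param p P-values in \[0, 1\].
#' @return Q-values (BH-adjusted p-values), same length.
#' @export
bh_correct <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Default post-filter thresholds for variant calling
#'
#' @param min_total_coverage Minimum total (both-strand) reads required in
#'   both the sample and the matched control (default > 50).
#' @param min_support Minimum reads supporting the variant (default 5).
#' @param merge_distance Calls within this many bases of one another in the
#'   same sample are merged into a single spanning deletion record (default 5).
#' @param q_cutoff BH q-value cutoff (default 0.05).
#' @param germline_vaf Control VAF above which a variant is treated as a
#'   germline heterozygote and removed (default 0.3).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_total_coverage = 50, min_support = 5,
                          merge_distance = 5, q_cutoff = 0.05,
                          germline_vaf = 0.3) {
  stopifnot(min_total_coverage > 0, min_support > 0, merge_distance > 0,
            q_cutoff > 0)
  structure(list(min_total_coverage = min_total_coverage,
                 min_support = min_support, merge_distance = merge_distance,
                 q_cutoff = q_cutoff, germline_vaf = germline_vaf),
            class = "filter_config")
}

# Per-sample site/allele LRT table: one row per (sample, site, alt allele).
site_tests <- function(counts, model) {
  long <- counts_to_long(counts)
  wide <- long |>
    dplyr::inner_join(model$v, by = c("chrom", "pos", "ref", "strand", "allele")) |>
    dplyr::filter(.data$allele != .data$ref) |>
    tidyr::pivot_wider(id_cols = c("sample", "chrom", "pos", "ref", "allele"),
                       names_from = "strand",
                       values_from = c("count", "depth", "v_test")) |>
    dplyr::filter(.data$depth_fwd > 0, .data$depth_rev > 0)
  wide |>
    dplyr::mutate(
      p_value = lrt_site(.data$count_fwd, .data$count_rev,
                         .data$depth_fwd, .data$depth_rev,
                         .data$v_test_fwd, .data$v_test_rev, model$rho),
      vaf = (.data$count_fwd + .data$count_rev) /
            (.data$depth_fwd + .data$depth_rev),
      support = .data$count_fwd + .data$count_rev,
      coverage = .data$depth_fwd + .data$depth_rev)
}

merge_nearby_calls <- function(calls, merge_distance) {
  if (nrow(calls) == 0) return(calls)
  calls |>
    dplyr::group_by(.data$sample, .data$chrom) |>
    dplyr::arrange(.data$pos, .by_group = TRUE) |>
    dplyr::mutate(cluster = cumsum(c(1, diff(.data$pos) > merge_distance))) |>
    dplyr::group_by(.data$sample, .data$chrom, .data$cluster) |>
    dplyr::summarise(
      merged_from = list(dplyr::pick("pos", "alt", "vaf")),
      n_merged = dplyr::n(),
      end = max(.data$pos),
      ref = dplyr::first(.data$ref),
      alt = if (dplyr::n() > 1) "<DEL>" else dplyr::first(.data$alt),
      vaf = mean(.data$vaf),
      support = min(.data$support), coverage = min(.data$coverage),
      p_value = min(.data$p_value), q_value = min(.data$q_value),
      pos = min(.data$pos),
      .groups = "drop") |>
    dplyr::select("sample", "chrom", "pos", "end", "ref", "alt", "vaf",
                  "support", "coverage", "p_value", "q_value", "n_merged",
                  "merged_from") |>
    dplyr::arrange(.data$sample, .data$chrom, .data$pos)
}

#' Call subclonal variants against the background error model
#'
#' Full calling pipeline: a strand-aware beta-binomial likelihood-ratio test
#' per site and alternate allele, BH correction across all tests within each
#' sample, removal of variants also present in the matched control (either
#' significant there at the same cutoff, or at control VAF above the germline
#' guard), the coverage (> 50 total reads in sample and control) and support
#' (>= 5 reads) filters, and finally merging of calls within 5 bases of one
#' another in the same sample into a single spanning record whose VAF is the
#' average of the merged calls.
#'
#' @param sample_counts,control_counts Long count tables (see
#'   [fit_error_model()] for the format).
#' @param matched_control Sample identifier of the matched control within
#'   `control_counts`.
#' @param model An `error_model`; fitted from `control_counts` when `NULL`.
#' @param config A [filter_config()].
#' @return A tibble of calls (class `variant_calls`): `sample`, `chrom`,
#'   `pos`, `end`, `ref`, `alt`, `vaf`, `support`, `coverage`, `p_value`,
#'   `q_value`, `n_merged`, `merged_from`.
#' @export
call_variants <- function(sample_counts, control_counts, matched_control,
                          model = NULL, config = filter_config()) {
  check_count_table(sample_counts)
  check_count_table(control_counts)
  if (!matched_control %in% control_counts$sample)
    abort(sprintf("matched control '%s' not present in control_counts", matched_control))
  model <- model %||% fit_error_model(control_counts)

  tests <- site_tests(sample_counts, model) |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(q_value = bh_correct(.data$p_value)) |>
    dplyr::ungroup()
  calls <- tests |> dplyr::filter(.data$q_value < config$q_cutoff)

  # matched-control screen: same test in the matched salivary sample
  ctrl <- site_tests(
    dplyr::filter(control_counts, .data$sample == matched_control), model) |>
    dplyr::mutate(q_value = bh_correct(.data$p_value)) |>
    dplyr::transmute(.data$chrom, .data$pos, .data$allele,
                     ctrl_q = .data$q_value, ctrl_vaf = .data$vaf,
                     ctrl_coverage = .data$coverage)
  calls <- calls |>
    dplyr::left_join(ctrl, by = c("chrom", "pos", "allele")) |>
    dplyr::filter(is.na(.data$ctrl_q) |
                  !(.data$ctrl_q < config$q_cutoff |
                    .data$ctrl_vaf > config$germline_vaf))

  # coverage filter needs control coverage even where the control was untested
  ctrl_cov <- control_counts |>
    dplyr::filter(.data$sample == matched_control) |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(ctrl_total = sum(.data$depth), .groups = "drop")
  calls <- calls |>
    dplyr::left_join(ctrl_cov, by = c("chrom", "pos")) |>
    dplyr::filter(.data$coverage > config$min_total_coverage,
                  !is.na(.data$ctrl_total),
                  .data$ctrl_total > config$min_total_coverage,
                  .data$support >= config$min_support) |>
    dplyr::transmute(.data$sample, .data$chrom, .data$pos, .data$ref,
                     alt = .data$allele, .data$vaf, .data$support,
                     .data$coverage, .data$p_value, .data$q_value)

  out <- merge_nearby_calls(calls, config$merge_distance)
  class(out) <- c("variant_calls", class(out))
  out
}

#' Spike-in benchmark of the variant caller
#'
#' Monte-Carlo validation of sensitivity and false discovery rate: synthetic
#' control and sample count matrices are generated with [simulate_counts()],
#' variants are spiked at the requested VAFs, the full [call_variants()]
#' pipeline is run, and per-VAF sensitivity plus the overall observed FDR are
#' scored against the spike-in truth table.
#'
#' @param vafs VAF grid for the spiked variants.
#' @param n_reps Monte-Carlo replicates per VAF.
#' @param spikes_per_rep Number of spiked sites per replicate.
#' @param n_controls,n_sites,depth_per_strand,rho_true,seed Passed to
#'   [spike_config()].
#' @param config A [filter_config()].
#' @return A list with `sensitivity` (tibble: vaf, n_spiked, n_found,
#'   sensitivity, se), `fdr` (observed FDR with a Monte-Carlo standard
#'   error), `n_calls`, `n_false`.
#' @export
benchmark_spikein <- function(vafs = c(0.02, 0.05, 0.1), n_reps = 3,
                              spikes_per_rep = 20, n_controls = 30,
                              n_sites = 1000, depth_per_strand = 500,
                              rho_true = 1e-3, seed = 1,
                              config = filter_config()) {
  set.seed(seed)
  res <- purrr::map(vafs, function(v) {
    purrr::map(seq_len(n_reps), function(rep) {
      spikes <- tibble(pos = sample.int(n_sites, spikes_per_rep),
                       vaf = v)
      cfg <- spike_config(n_controls = n_controls, n_samples = 1,
                          n_sites = n_sites,
                          depth_per_strand = depth_per_strand,
                          rho_true = rho_true, spikes = spikes,
                          seed = sample.int(2^30, 1))
      sim <- simulate_counts(cfg)
      calls <- call_variants(sim$samples, sim$controls,
                             matched_control = "control_01", config = config)
      truth_key <- paste(sim$truth$chrom, sim$truth$pos, sim$truth$alt)
      flat <- flatten_calls(calls)
      call_key <- paste(flat$chrom, flat$pos, flat$alt)
      tibble(vaf = v, n_spiked = nrow(sim$truth),
             n_found = sum(truth_key %in% call_key),
             n_calls = nrow(flat),
             n_false = sum(!call_key %in% truth_key))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  sens <- res |>
    dplyr::group_by(.data$vaf) |>
    dplyr::summarise(n_spiked = sum(.data$n_spiked),
                     n_found = sum(.data$n_found), .groups = "drop") |>
    dplyr::mutate(sensitivity = .data$n_found / .data$n_spiked,
                  se = sqrt(.data$sensitivity * (1 - .data$sensitivity) /
                              .data$n_spiked))
  n_calls <- sum(res$n_calls); n_false <- sum(res$n_false)
  fdr <- if (n_calls > 0) n_false / n_calls else NA_real_
  list(sensitivity = sens, fdr = fdr,
       fdr_se = if (n_calls > 0) sqrt(fdr * (1 - fdr) / n_calls) else NA_real_,
       n_calls = n_calls, n_false = n_false, detail = res)
}

# expand merged records back to their constituent (pos, alt) pairs for scoring
flatten_calls <- function(calls) {
  if (nrow(calls) == 0)
    return(tibble(sample = character(), chrom = character(),
                  pos = integer(), alt = character()))
  calls |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$.row) |>
    dplyr::reframe(sample = .data$sample, chrom = .data$chrom,
                   pos = .data$merged_from[[1]]$pos,
                   alt = .data$merged_from[[1]]$alt) |>
    dplyr::select(-".row")
}
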
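#' Configuration for synthetic strand-specific count matrices
#'
#' Describes a panel in the style of deep targeted sequencing of normal
#' epidermis: matched control samples that define the background error model,
#' epidermal samples, and optional spiked subclonal variants. Background
#' alternate-allele counts follow a beta-binomial with per-site, per-allele,
#' per-strand mean error fractions drawn log-uniformly over
#' `error_range` (error rates vary with genomic location) and a single
#' overdispersion `rho_true`.
#'
#' @param n_controls,n_samples Numbers of control and test samples.
#' @param n_sites Number of captured positions.
#' @param depth_per_strand Mean per-strand coverage (total depth is about
#'   twice this; 500/strand emulates 1000x panels).
#' @param rho_true True overdispersion of the background noise.
#' @param error_range Range (log-uniform) of mean error fractions.
#' @param spikes Tibble with columns `pos`, `vaf` and optionally `alt` and
#'   `sample`: subclonal variants added to test samples. VAFs must lie in
#'   (0, 0.5]; alleles default to a random non-reference base; samples default
#'   to the first test sample.
#' @param strand_bias If `TRUE`, spikes are placed on the forward strand only
#'   (an artefact mode for probing the strand-aware null); by default genuine
#'   variants are present equally on both strands.
#' @param seed RNG seed; generation is fully reproducible.
#' @return A list of class `spike_config`.
#' @export
spike_config <- function(n_controls = 10, n_samples = 1, n_sites = 500,
                         depth_per_strand = 500, rho_true = 1e-3,
                         error_range = c(1e-5, 10^-2.5), spikes = NULL,
                         strand_bias = FALSE, seed = 1) {
  spikes <- spikes %||% tibble(pos = integer(), vaf = numeric())
  stopifnot(n_controls >= 2, n_samples >= 1, n_sites >= 1,
            depth_per_strand >= 1, rho_true > 0)
  if (nrow(spikes) > 0) {
    if (any(spikes$pos < 1 | spikes$pos > n_sites))
      abort("spike at out-of-range site")
    if (any(spikes$vaf <= 0 | spikes$vaf > 0.5))
      abort("spike VAFs must lie in (0, 0.5]")
  }
  structure(list(n_controls = n_controls, n_samples = n_samples,
                 n_sites = n_sites, depth_per_strand = depth_per_strand,
                 rho_true = rho_true, error_range = error_range,
                 spikes = spikes, strand_bias = strand_bias, seed = seed),
            class = "spike_config")
}

rbetabinom_mu <- function(n, size, mu, rho) {
  out <- integer(n)
  pos <- mu > 0
  if (any(pos)) {
    a <- mu[pos] * (1 - rho) / rho
    b <- (1 - mu[pos]) * (1 - rho) / rho
    p <- rbeta(sum(pos), a, b)
    out[pos] <- rbinom(sum(pos), size[pos], p)
  }
  out
}

#' Simulate strand-specific count matrices with spiked subclones
#'
#' Generates control and test sample count tables under the beta-binomial
#' background model of [spike_config()], adds binomially sampled variant reads
#' at each spiked site (on both strands by default), and returns the truth
#' table needed to score any caller output.
#'
#' @param config A [spike_config()].
#' @return A list with `samples` and `controls` (long count tables with
#'   columns `sample`, `chrom`, `pos`, `ref`, `strand`, `A`, `C`, `G`, `T`,
#'   `DEL`, `depth`) and `truth` (tibble: `sample`, `chrom`, `pos`, `ref`,
#'   `alt`, `vaf`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "spike_config"))
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  alleles <- c(bases, "DEL")
  n_sites <- config$n_sites
  ref <- sample(bases, n_sites, replace = TRUE)

  # per site x allele x strand mean error fraction, log-uniform across sites
  lo <- log(config$error_range[1]); hi <- log(config$error_range[2])
  err <- array(exp(runif(n_sites * 5 * 2, lo, hi)), dim = c(n_sites, 5, 2),
               dimnames = list(NULL, alleles, c("fwd", "rev")))
  for (k in seq_along(alleles)) err[ref == alleles[k], k, ] <- 0

  gen_sample <- function(id) {
    purrr::map(c("fwd", "rev"), function(strand) {
      depth <- rpois(n_sites, config$depth_per_strand)
      cnt <- sapply(seq_along(alleles), function(k)
        rbetabinom_mu(n_sites, depth, err[, k, strand], config$rho_true))
      colnames(cnt) <- alleles
      # cap rare overshoot so alternate counts never exceed coverage
      tot <- rowSums(cnt)
      over <- tot > depth
      if (any(over)) cnt[over, ] <- floor(cnt[over, ] * depth[over] / tot[over])
      refn <- depth - rowSums(cnt)
      cnt[cbind(seq_len(n_sites), match(ref, alleles))] <- refn
      tibble(sample = id, chrom = "chr1", pos = seq_len(n_sites), ref = ref,
             strand = strand, as_tibble(cnt), depth = depth)
    }) |> purrr::list_rbind()
  }

  controls <- purrr::map(sprintf("control_%02d", seq_len(config$n_controls)),
                         gen_sample) |> purrr::list_rbind()
  samples <- purrr::map(sprintf("sample_%02d", seq_len(config$n_samples)),
                        gen_sample) |> purrr::list_rbind()

  spikes <- config$spikes
  truth <- tibble(sample = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), vaf = numeric())
  if (nrow(spikes) > 0) {
    if (!"sample" %in% names(spikes)) spikes$sample <- "sample_01"
    if (!"alt" %in% names(spikes))
      spikes$alt <- vapply(spikes$pos, function(p)
        sample(setdiff(bases, ref[p]), 1), character(1))
    for (i in seq_len(nrow(spikes))) {
      sp <- spikes[i, ]
      strands <- if (config$strand_bias) "fwd" else c("fwd", "rev")
      for (strand in strands) {
        row <- which(samples$sample == sp$sample & samples$pos == sp$pos &
                       samples$strand == strand)
        extra <- rbinom(1, samples$depth[row], sp$vaf)
        refcol <- ref[sp$pos]
        take <- min(extra, samples[[refcol]][row])
        samples[[sp$alt]][row] <- samples[[sp$alt]][row] + take
        samples[[refcol]][row] <- samples[[refcol]][row] - take
      }
    }
    truth <- tibble(sample = spikes$sample, chrom = "chr1", pos = spikes$pos,
                    ref = ref[spikes$pos], alt = spikes$alt, vaf = spikes$vaf)
  }
  list(samples = samples, controls = controls, truth = truth)
}

#' Sample clone sizes from the model distributions
#'
#' Draws clone sizes from one of the closed-form clone-size laws: the
#' neutral-drift distribution \eqn{P_n \propto e^{-n/r\lambda t}/n}
#' (`"neutral"`, integer sizes by inverse CDF), the boundary-nucleation
#' density `|M(A)|` (`"boundary_cubic"`, inverse-cubic tail), the
#' exponential-growth density \eqn{\propto A^{-2}} (`"exponential_square"`),
#' or a pure power law with arbitrary exponent (`"custom_powerlaw"`).
#'
#' @param model Model name.
#' @param params Named list of model parameters: `r_lambda_t` (neutral);
#'   `sigma`, `R` (boundary_cubic); `b`, `T_obs`, `sigma`
#'   (exponential_square); `exponent`, `xmin`, `xmax` (custom_powerlaw).
#' @param n_clones Number of clones to draw.
#' @param detect_vaf Detection threshold recorded with the sample.
#' @param seed RNG seed.
#' @return A tibble of class `clone_size_sample` with column `size`, plus the
#'   generating model and parameters as attributes.
#' @export
sample_clone_sizes <- function(model = c("neutral", "boundary_cubic",
                                         "exponential_square",
                                         "custom_powerlaw"),
                               params = list(), n_clones = 1000,
                               detect_vaf = 0.007, seed = 1) {
  model <- match.arg(model)
  stopifnot(n_clones >= 1)
  set.seed(seed)
  sizes <- switch(model,
    neutral = {
      a <- params$r_lambda_t %||% 500
      nmax <- max(10, ceiling(a * 40))
      n <- seq_len(nmax)
      w <- exp(-n / a) / n
      sample(n, n_clones, replace = TRUE, prob = w)
    },
    boundary_cubic = {
      sigma <- params$sigma %||% 1
      R <- params$R %||% 100
      grid <- exp(seq(log(sigma^2 / 10), log(0.5 * sigma * R^2),
                      length.out = 4096))
      dens <- boundary_M(grid, sigma, R)
      cdf <- cumsum(dens * c(diff(grid)[1], diff(grid)))
      cdf <- cdf / max(cdf)
      stats::approx(cdf, grid, runif(n_clones), rule = 2)$y
    },
    exponential_square = {
      b <- params$b %||% 1
      T_obs <- params$T_obs %||% 9
      sigma <- params$sigma %||% 1
      a <- pi * (sigma / 2)^2
      amax <- a * exp(b * T_obs)
      u <- runif(n_clones)  # inverse CDF of A^-2 on [a, amax]
      1 / (1 / a - u * (1 / a - 1 / amax))
    },
    custom_powerlaw = {
      k <- params$exponent %||% -3
      xmin <- params$xmin %||% 1
      xmax <- params$xmax %||% 1e4
      stopifnot(k < -1)
      u <- runif(n_clones)  # inverse CDF of x^k on [xmin, xmax]
      g <- k + 1
      (xmin^g + u * (xmax^g - xmin^g))^(1 / g)
    })
  structure(tibble(size = sizes),
            class = c("clone_size_sample", class(tibble())),
            model = model, params = params, detect_vaf = detect_vaf)
}

#' Assign substitution classes from a mutational spectrum
#'
#' Draws `n_mutations` substitutions from a probability vector over the 12
#' directional substitution classes (or the 6 pyrimidine-collapsed classes).
#' The default spectrum is strongly C>T-weighted, emulating the dominance of
#' C>T transitions characteristic of UV-induced mutagenesis (the default
#' weights are illustrative fixture values). A random trinucleotide context
#' consistent with the reference base is attached.
#'
#' @param n_mutations Number of mutations to draw.
#' @param spectrum Named probability vector over substitution classes like
#'   `"C>T"`; must sum to 1.
#' @param seed RNG seed.
#' @return A tibble with columns `class`, `ref`, `alt`, `context`.
#' @export
uv_spectrum_assign <- function(n_mutations,
                               spectrum = c("C>T" = 0.65, "C>A" = 0.06,
                                            "C>G" = 0.04, "T>A" = 0.05,
                                            "T>C" = 0.12, "T>G" = 0.03,
                                            "G>A" = 0.03, "A>G" = 0.02),
                               seed = 1) {
  if (abs(sum(spectrum) - 1) > 1e-8) abort("spectrum must sum to 1")
  classes <- names(spectrum)
  ok <- grepl("^[ACGT]>[ACGT]$", classes)
  if (!all(ok)) abort(sprintf("unknown substitution class '%s'", classes[!ok][1]))
  set.seed(seed)
  cls <- sample(classes, n_mutations, replace = TRUE, prob = spectrum)
  ref <- substr(cls, 1, 1)
  alt <- substr(cls, 3, 3)
  bases <- c("A", "C", "G", "T")
  context <- paste0(sample(bases, n_mutations, replace = TRUE), ref,
                    sample(bases, n_mutations, replace = TRUE))
  tibble(class = cls, ref = ref, alt = alt, context = context)
}
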
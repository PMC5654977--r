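# Independent oracles used across the suite; deliberately naive
# implementations kept separate from the package code paths.

# step-up BH by direct definition: q_(i) = min_{j >= i} min(1, m p_(j) / j)
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * (m / seq_len(m)))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# recursive clone sizes by per-site ancestor walking over the lattice
recursive_sizes_brute <- function(state) {
  tree <- state$tree
  parent <- tree$parent
  rec <- numeric(nrow(tree))
  labs <- state$label[state$kind != 0L]
  for (lab in labs) {
    l <- lab
    repeat {
      rec[l + 1L] <- rec[l + 1L] + 1
      p <- parent[l + 1L]
      if (is.na(p)) break
      l <- p
    }
  }
  rec
}

# forge a lattice state with an explicit label matrix (contiguous labels
# 0..k-1, each a child of the root unless parents given)
forge_state <- function(kind, label, parent = NULL, q = NULL,
                        mode = "homogeneous", diff_map = NULL) {
  k <- max(label) + 1L
  parent <- parent %||% c(NA_integer_, rep(0L, k - 1L))
  live <- tabulate(label[kind != 0L] + 1L, nbins = k)
  tree <- tibble::tibble(
    label = 0:(k - 1L), parent = parent, birth_day = 0L,
    class = c("root", rep("neutral", k - 1L)),
    live = as.numeric(live), active = TRUE)
  structure(list(kind = kind, label = label,
                 q = q %||% matrix(0L, nrow(kind), ncol(kind)),
                 tree = tree, time = 0L, mode = mode, diff_map = diff_map),
            class = "lattice_state")
}

# tiny hand-built count tables for exact caller fixtures: every control has
# `err` alternate reads so the background is non-degenerate
toy_counts <- function(samples, n_sites = 30, depth = 300, ref = "A",
                       err_allele = "G", err = 1,
                       spikes = NULL) {
  rows <- list()
  for (s in samples) {
    for (strand in c("fwd", "rev")) {
      tab <- tibble::tibble(
        sample = s, chrom = "chr1", pos = seq_len(n_sites), ref = ref,
        strand = strand, A = 0L, C = 0L, G = 0L, T = 0L, DEL = 0L,
        depth = as.integer(depth))
      tab[[err_allele]] <- as.integer(err)
      tab[[ref]] <- as.integer(depth - err)
      # spikes: tibble(sample, pos, alt, reads[, depth]); alt must differ
      # from ref and err_allele so the arithmetic stays independent
      if (!is.null(spikes)) {
        for (i in seq_len(nrow(spikes))) {
          sp <- spikes[i, ]
          if (sp$sample != s) next
          j <- sp$pos
          if ("depth" %in% names(sp) && !is.na(sp$depth))
            tab$depth[j] <- as.integer(sp$depth)
          tab[[sp$alt]][j] <- as.integer(sp$reads)
          tab[[ref]][j] <- as.integer(tab$depth[j] - err - sp$reads)
        }
      }
      rows[[length(rows) + 1L]] <- tab
    }
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
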
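test_that("hexagonal neighbourhoods have coordination number 6 and are symmetric", {
  dims <- c(10, 9)
  nb <- hex_neighbors(c(5, 5), dims)
  expect_equal(nrow(nb), 6)
  expect_equal(nrow(unique(nb)), 6)

  set.seed(42)
  for (boundary in c("torus", "clip")) {
    d <- if (boundary == "torus") c(8, 7) else c(7, 6)
    for (i in 1:200) {
      s <- c(sample(d[1], 1), sample(d[2], 1))
      for (j in seq_len(nrow(hex_neighbors(s, d, boundary)))) {
        nbj <- hex_neighbors(s, d, boundary)[j, ]
        back <- hex_neighbors(nbj, d, boundary)
        expect_true(any(back[, 1] == s[1] & back[, 2] == s[2]))
      }
    }
  }
})

test_that("clipped corner sites have 2-3 neighbours per the odd-row offset scheme", {
  # hand-enumerated for odd-r offsets: top-left corner (even row) keeps
  # only (0,+1) and (+1,0); top-right corner keeps 3
  tl <- hex_neighbors(c(1, 1), c(4, 5), "clip")
  expect_equal(nrow(tl), 2)
  expect_setequal(paste(tl[, 1], tl[, 2]), c("1 2", "2 1"))
  tr <- hex_neighbors(c(1, 5), c(4, 5), "clip")
  expect_equal(nrow(tr), 3)
  expect_error(hex_neighbors(c(0, 1), c(4, 5)), "out of range")
})

test_that("zero rates freeze the lattice and duration 0 is rejected", {
  p <- sim_params(10, 10, lam = 0, omega = 0, duration = 10)
  sim <- run_lattice(p, seed = 1)
  expect_true(all(sim$state$kind == 1L))
  expect_true(all(sim$state$label == 0L))
  expect_equal(nrow(sim$tree), 1)

  p0 <- sim_params(10, 10, duration = 0)
  expect_error(run_lattice(p0, seed = 1), "duration")
  init <- lattice_init(p0)
  expect_true(all(init$kind == 1L) && init$time == 0)
})

test_that("a lost cell with no occupied neighbour leaves a permanent vacancy", {
  p <- sim_params(1, 1, lam = 7, omega = 0, duration = 5, boundary = "clip")
  sim <- run_lattice(p, seed = 3)
  expect_equal(sim$state$kind[1, 1], 0L)
  expect_equal(nrow(sim$clones), 0)
})

test_that("daily stem losses match the binomial expectation", {
  # distinct labels everywhere make deaths observable: a death either leaves
  # a vacancy or gets refilled under a neighbour's label
  H <- W <- 40
  N <- H * W
  p <- sim_params(W, H, lam = 0.5, omega = 0, duration = 1)
  set.seed(99)
  deaths <- replicate(100, {
    st <- forge_state(matrix(1L, H, W), matrix(0:(N - 1L), H, W))
    st2 <- lattice_step(st, p)
    sum(st2$label != matrix(0:(N - 1L), H, W) | st2$kind == 0L)
  })
  expected <- N * 0.5 / 7
  mc_se <- sqrt(N * (0.5 / 7) * (1 - 0.5 / 7)) / sqrt(100)
  expect_lt(abs(mean(deaths) - expected), 3 * mc_se)
})

test_that("tree live counts match the lattice and recursive sizes match brute force", {
  p <- sim_params(24, 24, omega = 2e-2, duration = 60)
  sim <- run_lattice(p, seed = 5, purge_every = 0)
  live <- tabulate(sim$state$label + 1L, nbins = nrow(sim$tree))
  expect_equal(as.numeric(live), sim$tree$live)
  expect_gt(nrow(sim$tree), 50)

  cs <- clone_sizes(sim)
  brute <- recursive_sizes_brute(sim$state)
  expect_equal(cs$cells, brute[cs$label + 1L])
  # root clone spans every occupied site
  expect_equal(cs$cells[cs$label == 0], sum(sim$state$kind != 0L))
  expect_error(clone_sizes(sim, label = max(cs$label) + 1000L), "unknown")
})

test_that("recursive sums add a parent's own cells to all descendant cells", {
  kind <- matrix(1L, 2, 3)
  label <- matrix(c(1L, 2L, 2L, 3L, 3L, 3L), 2, 3)
  st <- forge_state(kind, label, parent = c(NA, 0L, 1L, 1L))
  cs <- clone_sizes(st)
  expect_equal(cs$cells[cs$label == 1], 6)  # 1 own + 2 + 3 from children
  expect_equal(cs$cells[cs$label == 0], 6)
})

test_that("purging is observationally silent and seeds reproduce trajectories", {
  p <- sim_params(20, 20, omega = 1e-2, duration = 90)
  a <- run_lattice(p, seed = 7, purge_every = 0)
  b <- run_lattice(p, seed = 7, purge_every = 15)
  expect_identical(a$state$kind, b$state$kind)
  expect_identical(a$state$label, b$state$label)
  expect_identical(clone_sizes(a)[], clone_sizes(b)[])
  expect_lte(sum(b$tree$active), sum(a$tree$active))

  c2 <- run_lattice(p, seed = 7, purge_every = 0)
  expect_identical(a$clones, c2$clones)
})

test_that("two neutral labels at 50/50 drift as a martingale around one half", {
  H <- W <- 16
  p <- sim_params(W, H, omega = 0, duration = 20)
  set.seed(123)
  half <- matrix(rep(c(1L, 2L), each = H * W / 2), H, W)
  frac <- replicate(200, {
    st <- forge_state(matrix(1L, H, W), half)
    st <- lattice_step(st, p, n_days = 20)
    mean(st$label[st$kind != 0L] == 1L)
  })
  se <- stats::sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.5), 3 * se)
})

test_that("mutant clones grow faster as phi drops below lambda", {
  H <- W <- 30
  grow <- function(phi, seeds) {
    sapply(seeds, function(s) {
      set.seed(s)
      kind <- matrix(1L, H, W); label <- matrix(0L, H, W)
      kind[14:16, 14:16] <- 2L; label[14:16, 14:16] <- 1L
      st <- forge_state(kind, label)
      p <- sim_params(W, H, lam = 0.5, phi = phi, omega = 0, duration = 150)
      st <- lattice_step(st, p, n_days = 150)
      sum(st$kind == 2L)
    })
  }
  strong <- grow(0.1, 1:25)
  weak <- grow(0.45, 1:25)
  expect_gt(mean(strong), mean(weak))
})

test_that("migration swaps occur at rate kappa and never with kappa = 0", {
  p0 <- sim_params(6, 6, kappa = 0)
  st <- forge_state(matrix(1L, 6, 6), matrix(0:35, 6, 6))
  expect_identical(lattice_migrate(st, p0, gated = FALSE)$label, st$label)

  # forced swap on a 1x2 clipped lattice: contents exchange every sweep
  p1 <- sim_params(2, 1, kappa = 1, boundary = "clip")
  st2 <- forge_state(matrix(c(1L, 1L), 1, 2), matrix(c(0L, 1L), 1, 2))
  sw <- lattice_migrate(st2, p1, gated = FALSE)
  expect_equal(as.vector(sw$label), c(1L, 0L))
  sw2 <- lattice_migrate(sw, p1, gated = FALSE)
  expect_equal(as.vector(sw2$label), c(0L, 1L))
})

test_that("lattice energy follows the two-branch formula", {
  # stem cell, no TA neighbours, diff = 0 -> 0
  st <- forge_state(matrix(1L, 4, 4), matrix(0L, 4, 4))
  expect_equal(lattice_energy(st, c(2, 2), penalty_p = 100), 0)

  # TA cell with 3 stem neighbours, 1 empty neighbour, diff = 1 -> 3 - 1 + 0
  kind <- matrix(0L, 4, 4)
  kind[2, 2] <- 3L
  nb <- hex_neighbors(c(2, 2), c(4, 4), "torus")
  kind[nb[1, 1], nb[1, 2]] <- 1L
  kind[nb[2, 1], nb[2, 2]] <- 1L
  kind[nb[3, 1], nb[3, 2]] <- 1L
  kind[nb[4, 1], nb[4, 2]] <- 3L
  kind[nb[5, 1], nb[5, 2]] <- 3L
  # neighbour 6 left empty
  dm <- matrix(1L, 4, 4)
  st2 <- forge_state(kind, matrix(0L, 4, 4), diff_map = dm)
  expect_equal(lattice_energy(st2, c(2, 2), diff_map = dm, penalty_p = 100), 2)

  # stem cell with 2 TA neighbours, diff = 1, p = 100 -> 102
  kind3 <- matrix(0L, 4, 4)
  kind3[2, 2] <- 1L
  kind3[nb[1, 1], nb[1, 2]] <- 3L
  kind3[nb[2, 1], nb[2, 2]] <- 3L
  st3 <- forge_state(kind3, matrix(0L, 4, 4), diff_map = dm)
  expect_equal(lattice_energy(st3, c(2, 2), diff_map = dm, penalty_p = 100), 102)

  expect_error(lattice_energy(st2, c(4, 4)), "empty")
})

test_that("energy-gated migration never raises total lattice energy", {
  set.seed(31)
  H <- W <- 20
  dm <- make_diff_map(W, H, cluster_radius = 5, cluster_spacing = 12)
  kind <- matrix(sample(c(0L, 1L, 3L), H * W, replace = TRUE,
                        prob = c(0.1, 0.45, 0.45)), H, W)
  label <- ifelse(kind == 0L, -1L, 0L)
  st <- forge_state(kind, matrix(label, H, W), mode = "heterogeneous",
                    diff_map = dm)
  p <- sim_params(W, H, kappa = 1, penalty_p = 100)
  e <- total_lattice_energy(st, dm, 100)
  for (i in 1:20) {
    st <- lattice_migrate(st, p, gated = TRUE)
    e2 <- total_lattice_energy(st, dm, 100)
    expect_lte(e2, e + 1e-9)
    e <- e2
  }
  # a sorted configuration (stem inside clusters, TA outside) is stable
  sorted <- forge_state(ifelse(dm == 0L, 1L, 3L) + 0L,
                        matrix(0L, H, W), mode = "heterogeneous", diff_map = dm)
  sorted$kind <- ifelse(dm == 0L, 1L, 3L)
  before <- sorted$kind
  sorted <- lattice_migrate(sorted, p, gated = TRUE)
  expect_identical(sorted$kind, before)
})

test_that("TA cells stop dividing at q_max and nu = 0 reduces to stem dynamics", {
  # C at q_max next to a vacancy never divides
  p <- sim_params(2, 1, lam = 0, omega = 0, nu = 0, q_max = 4,
                  ta_div_rate = 1, ta_loss_rate = 0, boundary = "clip")
  st <- forge_state(matrix(c(3L, 0L), 1, 2), matrix(c(0L, -1L), 1, 2),
                    mode = "heterogeneous", diff_map = matrix(1L, 1, 2))
  st$q <- matrix(c(4L, 0L), 1, 2)
  out <- lattice_step(st, p, n_days = 5)
  expect_equal(out$kind[1, 2], 0L)

  # below the cap it divides and both daughters carry q + 1
  st$q <- matrix(c(2L, 0L), 1, 2)
  out2 <- lattice_step(st, p, n_days = 1)
  expect_equal(as.vector(out2$kind), c(3L, 3L))
  expect_equal(as.vector(out2$q), c(3L, 3L))

  # nu = 0 with no TA cells present behaves like the homogeneous model
  ph <- sim_params(10, 10, omega = 0, nu = 0, duration = 30)
  hom <- run_lattice(ph, seed = 9, mode = "homogeneous")
  het <- run_lattice(ph, seed = 9, mode = "heterogeneous",
                     diff_map = matrix(0L, 10, 10), init_empty_frac = 0)
  expect_identical(hom$state$kind, het$state$kind)
  expect_identical(hom$state$label, het$state$label)
})

test_that("advantaged mutants widen the clone-size range over a matched neutral control", {
  run_one <- function(theta, seed) {
    p <- sim_params(90, 90, omega = 1e-3, theta = theta, phi = 0.1,
                    nu = 0.1, q_max = 4, cluster_radius = 9,
                    cluster_spacing = 24, duration = 2 * 365)
    sim <- run_lattice(p, mode = "heterogeneous", seed = seed)
    cs <- sim$clones
    max(cs$vaf[cs$label != 0])
  }
  mutant <- sapply(1:3, function(s) run_one(3e-5, s))
  neutral <- sapply(1:3, function(s) run_one(0, s))
  expect_gt(mean(mutant) / mean(neutral), 3)
})
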
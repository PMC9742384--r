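test_that("layer sizing identities reproduce the reference networks", {
  t1 <- build_topology(4, 7, 1, seed = 1)
  expect_equal(t1$N_MF, 28)
  expect_equal(t1$N_GrC, 371)   # ceiling(28 * 53 / 4)
  expect_equal(t1$N_GoC, 1)
  expect_equal(t1$N_PC, 1)
  t2 <- build_topology(3, 7, 6, seed = 1)
  expect_equal(t2$N_MF, 21)
  expect_equal(t2$N_GrC, 279)   # ceiling(21 * 53 / 4) = 279 (rounded up)
  expect_equal(t2$N_PC, 6)
  t3 <- build_topology(1, 1, 1, seed = 1)
  expect_equal(t3$N_MF, 1)
  expect_equal(t3$N_GrC, 14)    # ceiling(53 / 4)
  expect_equal(n_neurons(t2), 21 + 279 + 1 + 6)
})

test_that("sizing identities hold across feature/MF combinations", {
  for (d in c(1, 2, 5)) for (npf in c(1, 4, 7)) {
    tp <- build_topology(d, npf, 2, seed = 3)
    expect_equal(tp$N_MF, d * npf)
    expect_equal(tp$N_GrC, ceiling(d * npf * 53 / 4))
  }
})

test_that("fan-in is exact and weights are drawn within their ranges", {
  tp <- build_topology(4, 7, 2, seed = 7)
  expect_true(all(rowSums(tp$W_mf_grc != 0) == 4))
  expect_true(all(rowSums(tp$W_grc_pc != 0) == 48))
  nz <- tp$W_mf_grc[tp$W_mf_grc != 0]
  expect_true(all(nz >= 0.01 & nz <= 0.09))
  expect_true(all(tp$W_mf_goc >= 0.01 & tp$W_mf_goc <= 0.09))
  expect_true(all(tp$W_goc_grc >= 0.01 & tp$W_goc_grc <= 0.09))
  expect_true(all(tp$W_grc_pc[tp$W_grc_pc != 0] == 0.01))
  # presynaptic lists sampled without replacement
  expect_true(all(apply(tp$presyn_mf, 1, anyDuplicated) == 0))
  # small granule layers: the Purkinje cell pools every granule cell
  tiny <- build_topology(1, 1, 1, seed = 1)
  expect_equal(tiny$grc_per_pc, tiny$N_GrC)
  expect_error(build_topology(1, 2, 1, mf_per_grc = 4), "exceeds")
})

test_that("spike indicator reads the discrete Dirac comb", {
  expect_equal(spike_indicator(10.0, t = 10.0, dt = 0.1), 1L)
  expect_equal(spike_indicator(10.0, t = 10.1, dt = 0.1), 0L)
  # conservation: indicators over all steps sum to the number of spikes
  train <- c(3.25, 50.25, 211.75)
  total <- sum(vapply((0:599) * 0.5, function(t)
    spike_indicator(train, t, 0.5), integer(1)))
  expect_equal(total, 3)
})

test_that("postsynaptic drive equals the brute-force weighted indicator sum", {
  set.seed(9)
  trains <- lapply(1:10, function(i) sort(runif(sample(0:6, 1), 0, 100)))
  w <- runif(10, 0.01, 0.09)
  for (t in c(0, 13.4, 57.2, 99.9)) {
    brute <- 0
    for (i in 1:10)
      brute <- brute + w[i] * any(trains[[i]] >= t & trains[[i]] < t + 0.1)
    expect_equal(psp_drive(w, trains, t, 0.1, gain = 100), 100 * brute)
  }
  # no presynaptic spikes -> zero drive; one spike at weight w -> gain * w
  expect_equal(psp_drive(w, trains, t = 200, dt = 0.1), 0)
  expect_equal(psp_drive(0.05, list(5), t = 5, dt = 0.1, gain = 1000), 50)
})

test_that("network simulation is deterministic and layer counts match", {
  tp <- build_topology(2, 7, 1, seed = 5)
  mf <- toy_mf_trains(14)
  a <- simulate_network(tp, mf, T = 300, dt = 0.1)
  b <- simulate_network(tp, mf, T = 300, dt = 0.1)
  expect_identical(a$grc, b$grc)
  expect_identical(a$pc, b$pc)
  expect_length(a$grc, tp$N_GrC)
  expect_length(a$goc, tp$N_GoC)
  expect_length(a$pc, tp$N_PC)
  expect_error(simulate_network(tp, mf[1:3]), "expected")
})

test_that("granule cells stay silent without mossy-fiber input", {
  tp <- build_topology(2, 7, 1, seed = 5)
  act <- simulate_network(tp, rep(list(numeric(0)), 14), T = 300, dt = 0.1)
  expect_true(all(lengths(act$grc) == 0))
})

test_that("removing Golgi inhibition never decreases a granule cell's spike count", {
  tp <- build_topology(2, 7, 1, seed = 11)
  mf <- toy_mf_trains(14)
  on <- simulate_network(tp, mf, goc_inhibition = TRUE)
  off <- simulate_network(tp, mf, goc_inhibition = FALSE)
  expect_true(all(off$counts$grc >= on$counts$grc))
})

test_that("Golgi inhibition increases granule-layer synchrony on a seeded example", {
  # fixed demonstration: pairwise correlation of 5 ms binned spike counts
  set.seed(7)
  X <- matrix(runif(20 * 4), 20, 4)
  enc <- fit_encoder(X)
  Xn <- minmax_normalize(X, enc$spec)
  tp <- build_topology(4, 7, 1, seed = 4)
  mf <- mf_spike_trains(encode_instance(Xn[4, ], enc))
  sync <- function(act) {
    active <- act$grc[lengths(act$grc) > 0]
    M <- sapply(active, function(tt) tabulate(pmin(floor(tt / 5) + 1, 60), nbins = 60))
    C <- suppressWarnings(cor(M))
    mean(C[upper.tri(C)], na.rm = TRUE)
  }
  s_on <- sync(simulate_network(tp, mf, goc_inhibition = TRUE))
  s_off <- sync(simulate_network(tp, mf, goc_inhibition = FALSE))
  expect_gt(s_on, s_off)
})

test_that("topologies survive a JSON round trip", {
  tp <- build_topology(2, 3, 2, seed = 13)
  f <- tempfile(fileext = ".json")
  topology_to_json(tp, f)
  tp2 <- topology_from_json(f)
  expect_equal(tp2$N_GrC, tp$N_GrC)
  expect_equal(tp2$W_mf_grc, tp$W_mf_grc, ignore_attr = TRUE)
  expect_equal(tp2$presyn_mf, tp$presyn_mf, ignore_attr = TRUE)
})
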
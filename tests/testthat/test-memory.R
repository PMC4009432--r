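test_that("instantiation is seed-deterministic with all counters zero", {
  cfg <- sdm_config(64, 300, fraction = 0.05, seed = 9)
  m1 <- sdm(cfg)
  m2 <- sdm(cfg)
  expect_identical(m1$addresses, m2$addresses)
  expect_true(all(m1$counters == 0))
  expect_identical(dim(m1$counters), c(300L, 64L))
  m3 <- sdm(sdm_config(64, 300, fraction = 0.05, seed = 10))
  expect_false(identical(m1$addresses, m3$addresses))
  withr::local_options(sdmemory.max_bytes = 1e6)
  expect_error(sdm(sdm_config(1000, 1e4, r = 451)), "resource-infeasible")
})

test_that("activation uses the inclusive Hamming ball", {
  store <- sdm(sdm_config(64, 400, r = 0, seed = 2))
  center <- store$addresses[5, ]
  expect_identical(sdm_activate(store, center), 5L)
  # radius n activates everything
  store$r <- 64L
  expect_identical(sdm_activate(store, random_bitvector(64, seed = 1)),
    seq_len(400L))
  # hand-crafted boundary: distances 0, 3, 4, 5 against radius 4
  store2 <- sdm(sdm_config(8, 4, r = 4, seed = 1))
  store2$addresses <- rbind(
    rep(0, 8),
    c(1, 1, 1, 0, 0, 0, 0, 0),
    c(1, 1, 1, 1, 0, 0, 0, 0),
    c(1, 1, 1, 1, 1, 0, 0, 0))
  store2$addr_ones <- rowSums(store2$addresses)
  expect_identical(sdm_activate(store2, rep(0L, 8)), c(1L, 2L, 3L))
  expect_error(sdm_activate(store2, rep(0L, 9)), "dimension mismatch")
})

test_that("mean activated count matches H times the activation probability", {
  store <- sdm(sdm_config(256, 2000, fraction = 0.01, seed = 4))
  counts <- sapply(1:100, function(i) {
    length(sdm_activate(store, random_bitvector(256, seed = 100 + i)))
  })
  expected <- 2000 * activation_probability(256, store$r)
  expect_lt(abs(mean(counts) - expected) / expected, 0.1)
})

test_that("writes update exactly the activated counters", {
  store <- tiny_store(seed = 5)
  ones <- rep(1L, 64)
  act <- sdm_activate(store, ones)
  sdm_write(store, ones)
  expect_true(all(store$counters[act, ] == 1))
  expect_true(all(store$counters[-act, ] == 0))
  # writing the complement at the same address cancels to zero
  sdm_write(store, ones, datum = 0L * ones)
  expect_true(all(store$counters == 0))
})

test_that("each write moves every dimension of every activated location by times", {
  store <- tiny_store(seed = 6)
  eta <- random_bitvector(64, seed = 11)
  act <- sdm_activate(store, eta)
  before <- store$counters
  sdm_write(store, eta, times = 3L)
  delta <- store$counters - before
  expect_true(all(rowSums(abs(delta))[act] == 64 * 3))
  expect_true(all(delta[-act, ] == 0))
})

test_that("rehearsal is linear: times = w equals w repeated writes, batched or not", {
  eta <- random_bitvector(64, seed = 12)
  nu <- random_bitvector(64, seed = 13)
  s1 <- tiny_store(seed = 7)
  sdm_write(s1, eta, times = 4L)
  sdm_write(s1, nu)
  s2 <- tiny_store(seed = 7)
  for (i in 1:4) sdm_write(s2, eta)
  sdm_write(s2, nu)
  expect_identical(s1$counters, s2$counters)
  s3 <- tiny_store(seed = 7)
  sdmemory:::write_many(s3, rbind(eta, nu), times = c(4, 1), chunk = 1L)
  expect_identical(s1$counters, s3$counters)
  expect_identical(s1$write_load, s3$write_load)
})

test_that("a write that activates nothing warns and leaves the store unchanged", {
  store <- sdm(sdm_config(64, 20, r = 0, seed = 3))
  eta <- random_bitvector(64, seed = 14)
  expect_warning(sdm_write(store, eta), "no hard locations")
  expect_true(all(store$counters == 0))
})

test_that("read-after-write identity holds for every seed", {
  for (seed in 1:5) {
    store <- tiny_store(seed = seed)
    eta <- random_bitvector(64, seed = 20 + seed)
    sdm_write(store, eta)
    expect_identical(sdm_read(store, eta), eta)
  }
})

test_that("an unwritten memory reads as fair coin flips", {
  store <- sdm(sdm_config(1000, 50, r = 1000, seed = 8))
  out <- sdm_read(store, random_bitvector(1000, seed = 30), seed = 31)
  expect_lt(abs(mean(out) - 0.5), 0.06)
  # empty activation set: warning plus fully random output
  store$r <- 0L
  expect_warning(sdm_read(store, random_bitvector(1000, seed = 32)),
    "no hard locations")
})

test_that("an unsaturated memory pulls moderate cues strictly closer to the item", {
  store <- sdm(sdm_config(256, 1e4, fraction = 1e-2, seed = 10))
  eta <- random_bitvector(256, seed = 40)
  sdm_write(store, eta)
  closer <- sapply(1:100, function(i) {
    cue <- make_cue_at_distance(eta, 80, seed = 200 + i)
    out <- sdm_read(store, cue, seed = 300 + i)
    hamming_distance(out, eta) < 80
  })
  expect_gte(sum(closer), 95)
})

test_that("mean output distance is non-decreasing in cue distance for a single item", {
  store <- sdm(sdm_config(256, 2000, fraction = 0.02, seed = 11))
  eta <- random_bitvector(256, seed = 50)
  sdm_write(store, eta)
  means <- sapply(c(20, 80, 160, 240), function(d) {
    mean(sapply(1:30, function(i) {
      cue <- make_cue_at_distance(eta, d, seed = d * 1000 + i)
      hamming_distance(sdm_read(store, cue, seed = d * 2000 + i), eta)
    }))
  })
  expect_true(all(diff(means) >= -2))
})

test_that("iterated reading converges immediately on a stored item", {
  store <- tiny_store(seed = 12)
  eta <- random_bitvector(64, seed = 60)
  sdm_write(store, eta)
  tr <- iterative_read(store, eta, target = eta, seed = 61)
  expect_s3_class(tr, "read_trajectory")
  expect_identical(tr$verdict, "converged")
  expect_identical(tr$iterations_used, 1L)
  expect_identical(tr$distances_to_target, 0L)
})

test_that("far cues in a saturated memory do not reach the target", {
  store <- sdm(sdm_config(256, 2000, fraction = 0.01, seed = 13))
  eta <- random_bitvector(256, seed = 70)
  sdm_write(store, eta)
  sdmemory:::write_many(store, random_items(300, 256, seed = 71))
  tr <- iterative_read(store, make_cue_at_distance(eta, 240, seed = 72),
    target = eta, seed = 73)
  expect_false(tr$verdict == "converged" &&
    tail(tr$distances_to_target, 1) == 0)
  expect_gt(tail(tr$distances_to_target, 1), 0)
})

test_that("trajectories are bit-exact prefixes across iteration budgets", {
  store <- sdm(sdm_config(256, 2000, fraction = 0.01, seed = 14))
  eta <- random_bitvector(256, seed = 80)
  sdm_write(store, eta)
  sdmemory:::write_many(store, random_items(150, 256, seed = 81))
  cue <- make_cue_at_distance(eta, 60, seed = 82)
  t1 <- iterative_read(store, cue, max_iters = 1, target = eta, seed = 90)
  t6 <- iterative_read(store, cue, max_iters = 6, target = eta, seed = 90)
  expect_identical(t1$iterates[1, ], t6$iterates[1, ])
  # a budget of one is a single read (tie stream derived per cue and step)
  single <- sdm_read(store, cue, seed = stream_seed(90, 1, 1))
  expect_identical(t1$iterates[1, ], single)
})

test_that("the binary container round-trips the store and validates on load", {
  store <- tiny_store(seed = 15)
  sdm_write(store, random_bitvector(64, seed = 100))
  sdm_write(store, random_bitvector(64, seed = 101), times = 2L)
  path <- withr::local_tempfile(fileext = ".sdm")
  save_sdm(store, path)
  back <- load_sdm(path)
  expect_identical(back$addresses, store$addresses)
  expect_identical(back$counters, store$counters)
  expect_identical(back$n, store$n)
  expect_identical(back$H, store$H)
  expect_identical(back$r, store$r)
  expect_identical(back$n_writes, store$n_writes)
  cue <- random_bitvector(64, seed = 102)
  expect_identical(sdm_read(back, cue, seed = 1),
    sdm_read(store, cue, seed = 1))
  writeLines("not a container", path)
  expect_error(load_sdm(path), "bad magic")
  store$counters[1, 1] <- 2^31
  expect_error(save_sdm(store, path), "overflow")
})
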
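test_that("cycle weight decays linearly between its endpoints", {
  expect_equal(cycle_weight(0, 1000), 200)
  expect_equal(cycle_weight(1000, 1000), 100)
  expect_equal(cycle_weight(500, 1000), 150)
  steps <- seq(0, 400, by = 40)
  w <- cycle_weight(steps, 400)
  expect_equal(diff(w), rep(-10, 10))   # constant slope
  expect_error(cycle_weight(5, 4), "step")
  expect_error(cycle_weight(1, 0), "total")
})

test_that("history buffer respects capacity and the 1/2 swap rule", {
  set.seed(1)
  buf <- history_buffer(50L)
  expect_equal(buffer_size(buf), 0)
  first <- buffer_offer(buf, "img1")
  expect_identical(first, "img1")       # empty buffer returns the offer

  for (i in 2:200) buffer_offer(buf, paste0("img", i))
  expect_equal(buffer_size(buf), 50)    # never exceeds capacity

  # at capacity, the offer is swapped for a stored image half the time
  swaps <- 0L
  n <- 10000L
  for (i in seq_len(n)) {
    offer <- paste0("new", i)
    got <- buffer_offer(buf, offer)
    if (!identical(got, offer)) swaps <- swaps + 1L
  }
  expect_equal(swaps / n, 0.5, tolerance = 0.04)   # 0.5 +- 0.02 band
  expect_equal(buffer_size(buf), 50)
})

test_that("discriminator batches compose 4 real / 2 new / 2 history", {
  set.seed(2)
  cfg <- training_config()
  reals <- as.list(1:6)
  fakes <- as.list(101:104)
  buf <- history_buffer(50L)

  # cold buffer: shortfall filled with additional new fakes -> (4, 4, 0)
  b0 <- compose_disc_batch(reals, fakes, buf, cfg)
  src0 <- vapply(b0, `[[`, "", "source")
  expect_length(b0, 8)
  expect_equal(sum(src0 == "real"), 4)
  expect_equal(sum(src0 == "new"), 4)
  expect_equal(sum(src0 == "history"), 0)

  # warm buffer: exact (4, 2, 2)
  for (i in 1:60) buffer_offer(buf, i * 1000)
  b1 <- compose_disc_batch(reals, fakes, buf, cfg)
  src1 <- vapply(b1, `[[`, "", "source")
  expect_length(b1, 8)
  expect_equal(sum(src1 == "real"), 4)
  expect_equal(sum(src1 == "new"), 2)
  expect_equal(sum(src1 == "history"), 2)
  lab <- vapply(b1, `[[`, 0, "label")
  expect_equal(sum(lab == 1), 4)

  expect_error(compose_disc_batch(reals[1:3], fakes, buf, cfg), "real")
  expect_error(compose_disc_batch(reals, fakes[1], buf, cfg), "fake")
})

test_that("age-balanced plans share one min-rule bin distribution", {
  set.seed(30)
  # n_A = (10, 30), n_B = (20, 20) over two decade bins -> q = (1/3, 2/3)
  agesA <- c(runif(10, 20, 29.9), runif(30, 30, 39.9))
  agesB <- c(runif(20, 20, 29.9), runif(20, 30, 39.9))
  plan <- age_balanced_plan(agesA, agesB, bin_width = 10)
  expect_equal(plan$q[plan$q > 0], c(1 / 3, 2 / 3))
  expect_equal(sum(plan$q), 1)

  # identical lists: q equals the empirical bin distribution
  set.seed(3)
  ages <- runif(60, 20, 80)
  pl2 <- age_balanced_plan(ages, ages, bin_width = 10)
  emp <- tabulate(findInterval(ages, pl2$edges, rightmost.closed = TRUE),
                  length(pl2$edges) - 1L)
  expect_equal(pl2$q, emp / sum(emp))

  # a bin empty in one site gets zero probability
  pl3 <- age_balanced_plan(c(25, 26, 45, 46), c(25, 27), bin_width = 10)
  expect_equal(pl3$q, c(1, 0, 0))   # bins 30-40 and 40-50 unusable

  expect_error(age_balanced_plan(c(25, 26), c(45, 46), bin_width = 10),
               "degenerate")

  # realized draws follow q within sampling error
  set.seed(4)
  draws <- plan_sample(plan, "A", 4000L)
  frac_young <- mean(draws <= 10)
  expect_equal(frac_young, 1 / 3, tolerance = 0.03)
  # expected age distribution identical across sites by construction
  drawsB <- plan_sample(plan, "B", 4000L)
  expect_equal(mean(drawsB <= 20), 1 / 3, tolerance = 0.03)
})

test_that("identity pretraining descends and reproduces under a fixed seed", {
  cfgs <- preset_site_configs()
  co <- normalize_cohort(generate_cohort(4, 20, 80, cfgs$siteA, 32, 31))
  vols <- lapply(co$phantoms, `[[`, "volume")
  set.seed(5)
  gen <- build_generator(generator_spec(depth = 2, base_channels = 4))
  res <- pretrain_identity(gen, vols, steps = 60, seed = 6)
  expect_lt(mean(tail(res$trace, 10)), mean(head(res$trace, 10)))

  set.seed(5)
  gen2 <- build_generator(generator_spec(depth = 2, base_channels = 4))
  res2 <- pretrain_identity(gen2, vols, steps = 60, seed = 6)
  expect_identical(res$gen$params, res2$gen$params)
})

test_that("a short CycleGAN run keeps its contracts", {
  cfgs <- preset_site_configs()
  coA <- normalize_cohort(generate_cohort(4, 20, 80, cfgs$siteA, 32,
                                          41, site_label = "siteA"), 32L)
  coB <- normalize_cohort(generate_cohort(4, 20, 80, cfgs$siteB, 32,
                                          42, site_label = "siteB"), 32L)
  gspec <- generator_spec(depth = 2, base_channels = 4)
  dspec <- discriminator_spec(layers = list(c(4, 2, 4), c(4, 2, 8),
                                            c(3, 1, 1)))
  cfg <- training_config(total_steps = 6, seed = 43)
  fit <- train_cyclegan(coA, coB, cfg, gen_spec = gspec, disc_spec = dspec)

  expect_equal(nrow(fit$trace), 6)
  expect_true(all(is.finite(as.matrix(fit$trace))))   # finite loss trace
  expect_equal(fit$trace$lambda[1], 200)

  # determinism of the full run
  fit2 <- train_cyclegan(coA, coB, cfg, gen_spec = gspec, disc_spec = dspec)
  expect_identical(fit$G_AB$params, fit2$G_AB$params)
  expect_identical(fit$trace, fit2$trace)

  # harmonized output is masked and non-negative
  out <- harmonize_volume(fit$G_AB, coA$phantoms[[1]]$volume)
  expect_identical(unique(out$data[coA$phantoms[[1]]$volume$mask == 0]), 0)
  expect_gte(min(out$data), 0)

  expect_error(training_config(mixed_precision = TRUE), "precision")
  expect_error(training_config(cycle_weight_start = 50,
                               cycle_weight_end = 100), "cycle_weight")
  expect_error(training_config(buffer_capacity = 1, n_old_fake = 2),
               "buffer_capacity")
})

test_that("identity pretraining makes step-0 cycle losses small", {
  cfgs <- preset_site_configs()
  coA <- normalize_cohort(generate_cohort(4, 20, 80, cfgs$siteA, 32,
                                          51), 32L)
  coB <- normalize_cohort(generate_cohort(4, 20, 80, cfgs$siteB, 32,
                                          52), 32L)
  gspec <- generator_spec(depth = 2, base_channels = 4)
  set.seed(7)
  gen <- build_generator(gspec)
  pre <- pretrain_identity(gen, lapply(c(coA$phantoms, coB$phantoms),
                                       `[[`, "volume"),
                           steps = 250, seed = 8)
  ho <- normalize_cohort(generate_cohort(1, 20, 80, cfgs$siteA, 32, 53),
                         32L)$phantoms[[1]]$volume
  rec <- harmonize_volume(pre$gen, ho)
  mae <- mean(abs(rec$data[ho$mask > 0] - ho$data[ho$mask > 0]))

  dspec <- discriminator_spec(layers = list(c(4, 2, 4), c(4, 2, 8),
                                            c(3, 1, 1)))
  cfg <- training_config(total_steps = 2, seed = 54)
  fit <- train_cyclegan(coA, coB, cfg, gen_spec = gspec, disc_spec = dspec,
                        init_gen = pre$gen)
  # cycle loss of identity-initialized generators starts small
  cyc0 <- (fit$trace$cycle_a[1] + fit$trace$cycle_b[1]) / 2 *
    fit$cfg$intensity_scale
  expect_lt(cyc0, 2 * max(mae, 1))
})
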
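test_that("growth series: noiseless doubling, determinism, errors", {
  cfg0 <- synth_config(seed = 1, noise_cv = 0)
  d <- gen_growth_series(cfg0, "0000", n_points = 3, dt = 1, n0 = 1000)
  r <- synth_config(seed = 1)$true_rates[["0000"]]
  expect_equal(d$count, 1000 * exp(r * 0:2))
  # exact doublings when the rate is ln 2
  cfg2 <- synth_config(seed = 1, noise_cv = 0,
                       true_rates = c("0000" = log(2)))
  expect_equal(gen_growth_series(cfg2, "0000", n_points = 3, dt = 1)$count,
               c(1000, 2000, 4000))

  cfg <- test_config()
  expect_identical(gen_growth_series(cfg, "1000"),
                   gen_growth_series(cfg, "1000"))
  expect_false(identical(gen_growth_series(cfg, "1000", replicate = 1),
                         gen_growth_series(cfg, "1000", replicate = 2)))
  expect_error(gen_growth_series(cfg, "2222"), "2222")
  expect_error(gen_growth_series(cfg, "0000", n_points = 2), "n_points")
})

test_that("growth generator + estimator recover the planted rate within 3 SE", {
  cfg <- synth_config(seed = 42, true_rates = c(g = 0.35))
  fits <- lapply(1:10, function(i) {
    fit_growth_rate(gen_growth_series(cfg, "g", n_points = 12, dt = 0.5,
                                      replicate = i))
  })
  for (f in fits) expect_lt(abs(f$rate - 0.35), 3 * f$se_rate + 1e-12)
  # and without bias in aggregate
  expect_lt(abs(mean(vapply(fits, `[[`, numeric(1), "rate")) - 0.35), 0.01)
})

test_that("size samples: degenerate sigma, median, cross-seed estimator stability", {
  cfg <- synth_config(seed = 1, size_params = list(
    tight = list(mu = log(50), sigma = 1e-9),
    wide = list(mu = log(50), sigma = 0.3)
  ))
  expect_true(all(abs(gen_size_samples(cfg, "tight", 100) - 50) < 1e-5))
  x <- gen_size_samples(cfg, "wide", 100000)
  expect_true(all(x > 0))
  expect_lt(abs(median(x) / 50 - 1), 0.01) # log-normal median = exp(mu)
  # distinct seeds give distinct vectors but the same fitted sigma
  cfg2 <- synth_config(seed = 2, size_params = cfg$size_params)
  y <- gen_size_samples(cfg2, "wide", 100000)
  expect_false(identical(x, y))
  expect_lt(abs(fit_lognormal(x)$sigma - fit_lognormal(y)$sigma), 0.01)
  expect_error(gen_size_samples(cfg, "wide", 0), "n must be")
})

test_that("sweep series: step limits and structure", {
  cfg <- synth_config(seed = 1, sweep_times = list(
    STEP = list(midpoint = 500, steepness = Inf)
  ))
  s <- gen_sweep_series(cfg, "STEP", c(400, 500, 600))
  expect_equal(s$true_f, c(0, 0.5, 1))
  expect_true(all(s$h_mut >= 0 & s$h_anc >= 0))
  expect_error(gen_sweep_series(cfg, "STEP", c(600, 400)), "sorted")
})

test_that("sweep generator feeds order inference that recovers the planted order", {
  cfg <- test_config() # midpoints BEM3 150 < NRP1 450 < BEM2 650
  gens <- seq(0, 1000, by = 50)
  tc <- dplyr::bind_rows(lapply(c("BEM2", "BEM3", "NRP1"), function(l) {
    gen_sweep_series(cfg, l, gens)
  }))
  ord <- infer_order(tc)
  expect_equal(ord$locus, c("BEM3", "NRP1", "BEM2"))
})

test_that("toy genome plants every variant class and is deterministic", {
  cfg <- test_config()
  toy <- gen_toy_genome_and_variants(cfg)
  expect_setequal(
    unique(toy$truth$effect),
    c("nonsense", "missense", "promoter", "rejected_synonymous",
      "rejected_intergenic")
  )
  toy2 <- gen_toy_genome_and_variants(cfg)
  expect_identical(as.character(toy$genome), as.character(toy2$genome))
  expect_identical(toy$variants, toy2$variants)
  # every evolved strain contains the ancestor background variants
  anc <- dplyr::filter(toy$variants, strain == "ancestor")
  for (s in c("A1", "A2", "A3")) {
    ev <- dplyr::filter(toy$variants, strain == s)
    expect_true(all(anc$pos %in% ev$pos))
  }
  expect_error(
    synth_config(cds_intervals = tibble::tibble(
      start = 1, end = 2, strand = "+", gene = "X")),
    "at least 3 bp"
  )
})

test_that("spore grid has the right capacity and uniform genotype draws", {
  cfg <- test_config()
  grid <- gen_spore_grid(cfg)
  expect_equal(nrow(grid), 810) # 9 x 9 x 10 plates
  counts <- table(grid$genotype)
  expect_equal(length(counts), 16)
  # binomial 99% band around 810/16 under uniform sampling
  band <- qbinom(c(0.005, 0.995), 810, 1 / 16)
  expect_true(all(counts >= band[1] & counts <= band[2]))
  # survival probability 1 means every such spore forms a colony
  cfg_all <- synth_config(seed = 1,
                          spore_survival = setNames(rep(1, 16),
                                                    all_genotypes(4)))
  g2 <- gen_spore_grid(cfg_all)
  expect_true(all(g2$survived))
})

test_that("polarity traces: immediate spots, planted latency recovery, empty cohort", {
  fast <- synth_config(seed = 1, polarity = list(
    imm = list(p_polarize = 1, mean_tfsc = 2, mean_polarized = 10,
               spot_probs = c(0, 1, 0, 0))
  ))
  tr <- gen_polarity_traces(fast, "imm", 30, frame_interval = 2)
  pc <- summarize_trace(tr)
  expect_true(all(pc$t_fs_c == 2)) # one frame interval for every cell
  expect_equal(nrow(gen_polarity_traces(fast, "imm", 0)), 0)

  planted <- synth_config(seed = 5, polarity = list(
    g = list(p_polarize = 1, mean_tfsc = 30, mean_polarized = 40,
             spot_probs = c(0.2, 0.6, 0.15, 0.05))
  ))
  co <- summarize_cohort(gen_polarity_traces(planted, "g", 200))
  se <- sd(summarize_trace(gen_polarity_traces(planted, "g", 200))$t_fs_c) /
    sqrt(200)
  expect_lt(abs(co$mean_t_fs_c - 30), 2 * se + 1)
  expect_error(gen_polarity_traces(planted, "g", 5, frame_interval = 5),
               "frame_interval")
})

test_that("substream seeds are deterministic and name-sensitive", {
  expect_identical(substream_seed(1, "a"), substream_seed(1, "a"))
  expect_false(substream_seed(1, "a") == substream_seed(1, "b"))
  expect_false(substream_seed(1, "a") == substream_seed(2, "a"))
  expect_true(substream_seed(.Machine$integer.max, "long stage name") >= 0)
})
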
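test_that("Poisson concentration closed forms and error conditions", {
  v <- 8.5e-4
  expect_identical(poisson_concentration(0, 20000, v)$lambda_hat, 0)
  expect_equal(poisson_concentration(10000, 20000, v)$lambda_hat, log(2),
               tolerance = 1e-12)
  expect_error(poisson_concentration(5, 0, v), class = "empty_run")
  expect_error(poisson_concentration(100, 100, v), class = "saturated_run")
  expect_error(poisson_concentration(-1, 100, v), class = "bad_counts")
  ce <- poisson_concentration(500, 2000, v, dilution = 10)
  expect_true(ce$ci95[1] <= ce$lambda_hat && ce$lambda_hat <= ce$ci95[2])
  expect_equal(ce$copies_per_ul, ce$lambda_hat / v * 10)
  # exact binomial option produces a containing interval too
  ce2 <- poisson_concentration(500, 2000, v, exact = TRUE)
  expect_true(ce2$ci95[1] <= ce2$lambda_hat && ce2$lambda_hat <= ce2$ci95[2])
})

test_that("lambda-hat matches a brute-force Monte-Carlo partition oracle", {
  # frozen from the closed form: k = 1813 of N = 20000
  ce <- poisson_concentration(1813, 20000, 8.5e-4)
  expect_equal(ce$lambda_hat, 0.09503, tolerance = 1e-4)
  expect_equal(ce$copies_per_ul, 111.8, tolerance = 1e-3)
  # oracle: simulate droplet loading at the estimated lambda and check the
  # positive count comes back around k
  set.seed(77)
  ks <- vapply(1:200, function(i) sum(stats::rpois(20000, ce$lambda_hat) > 0),
               numeric(1))
  se <- stats::sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - 1813), 4 * se)
})

test_that("VCN is the ploidy-scaled ratio to the Titin reference", {
  expect_equal(vcn(300, 200)$value, 3)
  expect_equal(vcn(0, 200)$value, 0)
  expect_equal(vcn(300, 200, ploidy = 1)$value, 1.5)
  expect_error(vcn(300, 0), class = "zero_reference")
})

test_that("HR efficiency uses the limiting vector and is scale-invariant", {
  expect_equal(hr_efficiency(2, 4, 5)$value, 50)
  expect_equal(hr_efficiency(0, 4, 5)$value, 0)
  expect_equal(hr_efficiency(2, 5, 4)$value, 50)  # limiting side switches
  for (s in c(0.1, 3, 1000))
    expect_equal(hr_efficiency(2 * s, 4 * s, 5 * s)$value, 50)
  expect_error(hr_efficiency(2, 0, 5), class = "zero_reference")
})

test_that("concatemer fraction sums junction reactions over total vector load", {
  expect_equal(concatemer_fraction(c(0.10, 0.10, 0.05, 0.05), 3, 3)$value, 5)
  expect_equal(concatemer_fraction(numeric(0), 3, 3)$value, 0)
  expect_equal(concatemer_fraction(0.3, 3, 3)$value, 5)
  expect_error(concatemer_fraction(0.3, 0, 0), class = "zero_reference")
  # raw-droplet variant on conc_estimates
  v <- 8.5e-4
  j <- poisson_concentration(50, 20000, v)
  c5 <- poisson_concentration(500, 20000, v)
  c3 <- poisson_concentration(500, 20000, v)
  raw <- concatemer_fraction(list(j), c5, c3, poisson_correct = FALSE)
  expect_equal(raw$value, 100 * 50 / 1000)
})

test_that("expression profile classifies specificity and flags contamination", {
  p <- expression_profile(list(REC_RT = 1000, FIVE_RT = 20, THREE_RT = 0))
  expect_true(p$specific)
  p2 <- expression_profile(list(REC_RT = 1000, FIVE_RT = 20, THREE_RT = 50))
  expect_false(p2$specific)
  p3 <- expression_profile(list(REC_RT = 100, FIVE_RT = 90, THREE_RT = 0))
  expect_false(p3$specific)
  expect_error(expression_profile(list(REC_RT = 1000, FIVE_RT = 0,
                                       THREE_RT = 0), minus_rt = 100),
               class = "genomic_contamination")
  expect_error(expression_profile(list(REC_RT = 1)), class = "bad_counts")
})

test_that("RT recovery: leak-to-recombined ratio reflects the simulated rates", {
  # population with known free 5' units and HR count
  pop <- sample_population(list(parse_structure("5+|HR|3+", 2000),
                                parse_structure("5+", 3000)), 0)
  eps <- 0.05; r <- 2
  ratios <- vapply(1:30, function(s) {
    tp <- simulate_transcripts(pop, leak_rate = eps, expr_rate = r, seed = s)
    tf <- transcript_fragments(tp)
    cfg <- ddpcr_config(n_droplets = 20000, seed = s + 500)
    sub <- panel_subset(dq_panel(), c("FIVE_RT", "THREE_RT", "REC_RT"))
    g <- gate_droplets(detect_droplets(partition_fragments(tf, cfg), sub,
                                       mode = "calls"), digestion = "none")
    conc <- run_concentrations(g)
    conc$FIVE_RT$copies_per_ul / conc$REC_RT$copies_per_ul
  }, numeric(1))
  expected <- (eps * 3000) / (r * 2000)
  expect_lt(abs(mean(ratios) - expected), 0.1 * expected)
})

test_that("quant_report assembles estimates, fold ratio and protocol flags", {
  out <- simulate_and_quantify(sim_params(host_genomes = 2000, seed = 31,
                                          concat_fraction = 0.15),
                               n_droplets = 8000)
  rep <- out$report
  expect_s3_class(rep, "quant_report")
  expect_equal(rep$fold_hr_over_concat,
               rep$hr_pct$value / rep$concat_pct$value)
  co <- coef(rep)
  expect_named(co, c("vcn5", "vcn3", "vcn_rec", "hr_pct", "concat_pct",
                     "fold_hr_over_concat"))
  expect_true(all(co >= 0))
  expect_output(print(rep), "HR efficiency")
  expect_output(summary(rep), "per-assay")

  # hand-computed fold
  expect_equal(50 / 4, 12.5)
  # protocol mismatch: a VCN run without SmaI errors unless allowed
  g_bad <- structure(data.frame(assay = c("FIVE", "THREE", "REC", "TTN"),
                                k = c(10, 10, 5, 10), N = 1000),
                     class = c("gated_counts", "data.frame"),
                     droplet_volume = 8.5e-4, sample_volume = 20,
                     dilution = 1, digestion = "none")
  expect_error(quant_report(g_bad), class = "protocol_mismatch")
  rep2 <- quant_report(g_bad, allow_protocol_mismatch = TRUE)
  expect_true(length(rep2$flags) > 0)
})

test_that("report JSON serialization round-trips the headline numbers", {
  out <- simulate_and_quantify(sim_params(host_genomes = 1000, seed = 17,
                                          concat_fraction = 0.1),
                               n_droplets = 5000)
  path <- tempfile(fileext = ".json")
  write_report_json(out$report, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$hr_pct$value, out$report$hr_pct$value, tolerance = 1e-8)
  expect_equal(back$vcn5$value, out$report$vcn5$value, tolerance = 1e-8)
})
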
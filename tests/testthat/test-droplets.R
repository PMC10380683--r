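test_that("junction-class bookkeeping agrees with physical primer-pair enumeration", {
  cs <- dq_constructs(); panel <- dq_panel()
  # reaction contents per junction assay
  reaction_primers <- list(jxAB = c("A", "B"), jxCD = c("C", "D"),
                           jxAD = c("A", "D"), jxCB = c("C", "B"))
  cases <- list(
    # structure, expected flanking class, expected claiming assay (or NA)
    list("5+|HT|3+", "A|B", "jxAB"),
    list("3+|HT|5+", "C|D", "jxCD"),
    list("5+|TT|3-", "A|D", "jxAD"),
    list("5-|HH|3+", "B|C", "jxCB"),
    list("5+|TT|5-", "A|A", "jxAB"),
    list("3+|TT|3-", "D|D", "jxCD"),
    list("5-|HH|5+", "C|C", "jxCD"),
    list("3-|HH|3+", "B|B", "jxAB"),
    list("5+|HT|5+", "A|C", NA),
    list("3+|HT|3+", "B|D", NA))
  for (cse in cases) {
    f <- digest(pop1(cse[[1]]), "AleI", cs, panel)
    jx_frag <- Filter(function(fr) any(fr$jtype != "HR"), f$fragments)
    expect_length(jx_frag, 1L)
    fr <- jx_frag[[1]]
    expect_identical(fr$jclass[fr$jtype != "HR"], cse[[2]])
    claimed <- names(reaction_primers)[vapply(names(reaction_primers),
      function(nm) amplifiable(fr, panel$assays[[nm]]), logical(1))]
    if (is.na(cse[[3]])) {
      expect_length(claimed, 0L)
      # physically: no single two-primer reaction carries both required
      # primers, so every reaction's enumeration also comes up empty
      for (pr in reaction_primers)
        expect_false(oracle_pair_amplifiable(fr, pr))
    } else {
      expect_identical(claimed, cse[[3]])
      # the claiming reaction can physically amplify across the junction
      expect_true(oracle_pair_amplifiable(fr, reaction_primers[[cse[[3]]]]))
    }
  }
})

test_that("partitioning follows Poisson occupancy statistics", {
  cfg <- ddpcr_config(n_droplets = 20000, seed = 5)
  # empty population: all droplets empty
  f0 <- digest(sample_population(list(), 0),
               "none", dq_constructs(), dq_panel())
  occ0 <- partition_fragments(f0, cfg)
  expect_identical(sum(occ0$occupancy), 0L)

  # single class at lambda = ln 2: positive fraction ~ 0.5
  count <- log(2) * cfg$sample_volume / cfg$droplet_volume
  f1 <- structure(list(fragments = list(list(length = 100, kind = character(0),
                                             name = character(0), pos = numeric(0),
                                             strand = character(0), jpos = numeric(0),
                                             jtype = character(0), jclass = character(0),
                                             circular = FALSE, transcript_class = NULL)),
                       counts = count, enzymes = character(0)),
                  class = "fragment_population")
  occ1 <- partition_fragments(f1, cfg)
  phat <- mean(occ1$occupancy[, 1] > 0)
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / cfg$n_droplets))

  # two independent classes at lambda = 0.1: double-occupancy product law
  f2 <- f1
  f2$fragments <- c(f2$fragments, f2$fragments)
  f2$counts <- rep(0.1 * cfg$sample_volume / cfg$droplet_volume, 2)
  occ2 <- partition_fragments(f2, cfg)
  dbl <- mean(occ2$occupancy[, 1] > 0 & occ2$occupancy[, 2] > 0)
  p1 <- 1 - exp(-0.1)
  expect_lt(abs(dbl - p1^2), 3 * sqrt(p1^2 * (1 - p1^2) / cfg$n_droplets))

  # saturation guard
  f3 <- f1; f3$counts <- 11 * cfg$sample_volume / cfg$droplet_volume
  expect_error(partition_fragments(f3, cfg), class = "saturated_run")
})

test_that("amplitude clouds are additive over positive assays", {
  cs <- dq_constructs(); panel <- dq_panel()
  probe <- panel_subset(panel, c("FIVE", "THREE", "REC", "TTN"))
  # a population whose single fragment class carries FIVE and THREE targets
  # cannot exist (disjoint constructs), so use co-occupancy at high load
  pop <- sample_population(list(parse_structure("5+", 60000),
                                parse_structure("3+", 60000)), 0)
  cfg <- ddpcr_config(n_droplets = 500, noise_sd = 0, seed = 2)
  occ <- partition_fragments(digest(pop, "SmaI", cs, panel), cfg)
  dd <- detect_droplets(occ, probe, mode = "amplitude")
  calls <- detect_droplets(occ, probe, mode = "calls")
  lev <- calls$calls[, "FIVE"] * 1 + calls$calls[, "THREE"] * 2
  expect_identical(unname(dd$amplitudes[, "FAM"]),
                   unname(cfg$baseline + cfg$amp_unit * lev))
  # droplets positive for both FIVE (x1) and THREE (x2) sit in the level-3 cloud
  expect_gt(sum(lev == 3), 0)
  # empty droplets are baseline-only in both channels
  empty <- rowSums(occ$occupancy) == 0
  if (any(empty)) {
    expect_true(all(dd$amplitudes[empty, "FAM"] == cfg$baseline))
    expect_true(all(dd$amplitudes[empty, "VIC"] == cfg$baseline))
  }
})

test_that("noiseless amplitude gating reproduces calls-mode counts exactly", {
  cs <- dq_constructs(); panel <- dq_panel()
  probe <- panel_subset(panel, c("FIVE", "THREE", "REC", "TTN"))
  for (seed in c(1, 7, 23)) {
    out <- simulate_sample(sim_params(host_genomes = 2000, seed = seed))
    cfg <- ddpcr_config(n_droplets = 5000, noise_sd = 0, seed = seed + 100)
    occ <- partition_fragments(digest(out$population, "SmaI", cs, panel), cfg)
    g_amp <- gate_droplets(detect_droplets(occ, probe, mode = "amplitude"),
                           probe)
    g_calls <- gate_droplets(detect_droplets(occ, probe, mode = "calls"))
    expect_identical(g_amp$k[match(g_calls$assay, g_amp$assay)], g_calls$k)
  }
})

test_that("gating is monotone in thresholds and rejects inverted ones", {
  cs <- dq_constructs(); panel <- dq_panel()
  probe <- panel_subset(panel, c("FIVE", "THREE", "REC", "TTN"))
  out <- simulate_sample(sim_params(host_genomes = 2000, seed = 4))
  cfg <- ddpcr_config(n_droplets = 5000, noise_sd = 60, seed = 9)
  occ <- partition_fragments(digest(out$population, "SmaI", cs, panel), cfg)
  dd <- detect_droplets(occ, probe, mode = "amplitude")
  base <- cfg$baseline + cfg$amp_unit * (0:3)
  thr1 <- (base[-1] + base[-4]) / 2
  thr2 <- thr1; thr2[1] <- thr2[1] + 900  # raise first threshold past cloud 1
  g1 <- gate_droplets(dd, probe, thresholds = list(FAM = thr1, VIC = thr1))
  g2 <- gate_droplets(dd, probe, thresholds = list(FAM = thr2, VIC = thr1))
  expect_true(all(g2$k <= g1$k))
  expect_error(gate_droplets(dd, probe,
                             thresholds = list(FAM = rev(thr1), VIC = thr1)),
               class = "gating")
})

test_that("droplet CSVs round-trip with their metadata sidecars", {
  cs <- dq_constructs(); panel <- dq_panel()
  probe <- panel_subset(panel, c("FIVE", "THREE", "REC", "TTN"))
  out <- simulate_sample(sim_params(host_genomes = 1000, seed = 6))
  cfg <- ddpcr_config(n_droplets = 2000, noise_sd = 0, seed = 3)
  occ <- partition_fragments(digest(out$population, "SmaI", cs, panel), cfg)

  for (mode in c("calls", "amplitude")) {
    dd <- detect_droplets(occ, probe, mode = mode)
    path <- tempfile(fileext = ".csv")
    write_droplet_csv(dd, path, digestion = "SmaI")
    back <- read_droplet_csv(path)
    expect_identical(back$mode, mode)
    expect_identical(back$n_droplets, cfg$n_droplets)
    g1 <- gate_droplets(dd, probe)
    g2 <- gate_droplets(back, probe)
    expect_identical(g1$k, g2$k)
  }

  # all-negative calls give zero concentrations downstream
  neg <- structure(list(mode = "calls",
                        calls = matrix(FALSE, 100, 2,
                                       dimnames = list(NULL, c("FIVE", "THREE"))),
                        n_droplets = 100L, cfg = cfg,
                        panel_names = c("FIVE", "THREE")),
                   class = "droplet_dataset")
  g <- gate_droplets(neg)
  conc <- run_concentrations(g)
  expect_identical(conc$FIVE$copies_per_ul, 0)

  # malformed CSV errors with a parse condition
  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3"), bad)
  jsonlite::write_json(list(mode = "calls", n_droplets = 2,
                            droplet_volume = 8.5e-4, sample_volume = 20,
                            assays = list("a", "b")),
                       paste0(bad, ".meta.json"), auto_unbox = TRUE)
  expect_error(read_droplet_csv(bad), class = "dualAAVquant_error")
})
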
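test_that("limit cases: no HR and no concatemers give pure monomers", {
  out <- simulate_sample(sim_params(u5 = 3, u3 = 4, hr_fraction = 0,
                                    concat_fraction = 0, host_genomes = 500,
                                    seed = 11))
  expect_true(all(vapply(out$population$species, function(m)
    length(m$identities) == 1L, logical(1))))
  expect_identical(out$truth$R, 0L)
  expect_identical(out$truth$true_hr, 0)
  expect_identical(out$truth$true_concat, 0)
})

test_that("limit case: full HR consumes the limiting vector entirely", {
  out <- simulate_sample(sim_params(u5 = 5, u3 = 5, hr_fraction = 1,
                                    concat_fraction = 0, host_genomes = 500,
                                    seed = 12))
  expect_identical(out$truth$true_hr, 1)
  expect_identical(out$truth$R, min(out$truth$T5, out$truth$T3))
  # no chains: every species is a monomer or an HR dimer
  expect_true(all(vapply(out$population$species, function(m)
    length(m$identities) <= 2L, logical(1))))
})

test_that("unit conservation holds exactly for every seed", {
  for (seed in 1:25) {
    p <- sim_params(u5 = runif(1, 1, 6), u3 = runif(1, 1, 6),
                    hr_fraction = runif(1), concat_fraction = runif(1, 0, 0.5),
                    chain_length_p = runif(1, 0.2, 0.9),
                    host_genomes = 300, seed = seed)
    out <- simulate_sample(p)
    rc <- recount_units(out$population)
    expect_identical(rc$T5, out$truth$T5)
    expect_identical(rc$T3, out$truth$T3)
  }
})

test_that("ground_truth_metrics audits simulated populations consistently", {
  out <- simulate_sample(sim_params(concat_fraction = 0.2, host_genomes = 1000,
                                    seed = 3))
  gt2 <- ground_truth_metrics(out$population)
  expect_identical(gt2$T5, out$truth$T5)
  expect_identical(gt2$T3, out$truth$T3)
  expect_identical(gt2$R, out$truth$R)
  expect_identical(gt2$true_hr, out$truth$true_hr)
  expect_identical(gt2$true_concat, out$truth$true_concat)

  # hand-built cases
  gt <- ground_truth_metrics(pop1("5+|HR|3+", 10))
  expect_identical(c(gt$T5, gt$T3, gt$R), c(10L, 10L, 10L))
  expect_identical(nrow(gt$J), 0L)

  circ <- sample_population(list(
    molecule_species(c("five_prime", "three_prime"), c("+", "+"),
                     c("ITR_head_to_tail", "ITR_head_to_tail"),
                     topology = "circular", count = 1L)), 0L)
  gtc <- ground_truth_metrics(circ)
  expect_identical(sum(gtc$J$count), 2L)
  expect_identical(gtc$R, 0L)
})

test_that("seeded determinism: identical parameters give identical species tables", {
  p <- sim_params(concat_fraction = 0.15, host_genomes = 800, seed = 42)
  a <- simulate_sample(p); b <- simulate_sample(p)
  key <- function(pop) paste(vapply(pop$population$species, structure_string,
                                    character(1)),
                             vapply(pop$population$species, `[[`, integer(1),
                                    "count"), collapse = "&")
  expect_identical(key(a), key(b))
})

test_that("molecule construction rejects inconsistent junction orientations", {
  expect_error(molecule_species(c("five_prime", "three_prime"), c("+", "-"),
                                "HR"), class = "molecule_invalid")
  expect_error(molecule_species(c("five_prime", "five_prime"), c("+", "+"),
                                "ITR_tail_to_tail"), class = "molecule_invalid")
  expect_error(molecule_species(c("five_prime", "five_prime"), c("+", "-"),
                                character(0)), class = "molecule_invalid")
  m <- molecule_species(c("five_prime", "five_prime"), c("+", "-"),
                        "ITR_tail_to_tail")
  expect_identical(structure_string(m), "5+|TT|5-")
  expect_identical(structure_string(parse_structure("5+|HT|3+|TT|3-")),
                   "5+|HT|3+|TT|3-")
})

test_that("junction type choice follows orientation weights conditionally on the free end", {
  w <- c(2, 1, 1)  # HT, HH, TT
  out <- simulate_sample(sim_params(u5 = 5, u3 = 5, hr_fraction = 0,
                                    concat_fraction = 0.9,
                                    chain_length_p = 0.25,
                                    orientation_weights = w,
                                    host_genomes = 3000, seed = 21))
  # recount transitions from structure strings
  from_tail <- c(HT = 0, TT = 0); from_head <- c(HT = 0, HH = 0)
  for (m in out$population$species) {
    if (length(m$junctions) == 0) next
    for (j in seq_along(m$junctions)) {
      end <- if (m$orients[j] == "+") "tail" else "head"
      ty <- c(ITR_head_to_tail = "HT", ITR_head_to_head = "HH",
              ITR_tail_to_tail = "TT")[m$junctions[j]]
      if (end == "tail") from_tail[ty] <- from_tail[ty] + m$count
      else from_head[ty] <- from_head[ty] + m$count
    }
  }
  n_t <- sum(from_tail); n_h <- sum(from_head)
  expect_gt(n_t + n_h, 5000)
  p_ht_tail <- w[1] / (w[1] + w[3])
  p_ht_head <- w[1] / (w[1] + w[2])
  tol_t <- 3 * sqrt(p_ht_tail * (1 - p_ht_tail) / n_t)
  tol_h <- 3 * sqrt(p_ht_head * (1 - p_ht_head) / n_h)
  expect_lt(abs(from_tail["HT"] / n_t - p_ht_tail), tol_t)
  expect_lt(abs(from_head["HT"] / n_h - p_ht_head), tol_h)
})

test_that("transcript simulation matches its Poisson model", {
  pop0 <- pop1("5+", 100)
  tp <- simulate_transcripts(pop0, leak_rate = 0, expr_rate = 2, seed = 1)
  expect_identical(tp$counts[["five_leak"]], 0L)
  expect_identical(tp$counts[["recombined"]], 0L)  # R = 0
  expect_identical(tp$counts[["three_aberrant"]], 0L)

  pop_hr <- pop1("5+|HR|3+", 1000)
  recs <- vapply(1:100, function(s)
    simulate_transcripts(pop_hr, leak_rate = 0.02, expr_rate = 2,
                         seed = s)$counts[["recombined"]], numeric(1))
  se <- sqrt(2000 / 100)  # Poisson mean 2000, 100 replicates
  expect_lt(abs(mean(recs) - 2000), 3 * se)
})

test_that("species tables round-trip through TSV", {
  out <- simulate_sample(sim_params(concat_fraction = 0.2, host_genomes = 200,
                                    seed = 9))
  path <- tempfile(fileext = ".tsv")
  write_species_table(out$population, path)
  back <- read_species_table(path)
  expect_identical(back$host_genomes, out$population$host_genomes)
  gt <- ground_truth_metrics(back)
  expect_identical(gt$T5, out$truth$T5)
  expect_identical(gt$true_concat, out$truth$true_concat)
})

test_that("phi calibration hits the requested detectable junction fraction", {
  p0 <- sim_params(hr_fraction = 0.5, host_genomes = 5000, seed = 1)
  phi <- phi_for_concat_target(0.04, p0)
  tc <- vapply(1:20, function(s) {
    p <- p0; p$seed <- s; p$concat_fraction <- phi
    simulate_sample(p)$truth$true_concat
  }, numeric(1))
  expect_lt(abs(mean(tc) - 0.04), 0.004)
})
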
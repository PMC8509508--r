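test_that("generation is deterministic given config and seed", {
  cfg <- default_agep_config(n_reports = 400, seed = 8)
  a <- simulate_icsr(cfg)
  b <- simulate_icsr(cfg)
  expect_identical(a$entries, b$entries)
  expect_identical(a$meta, b$meta)
  c <- simulate_icsr(cfg, seed = 9)
  expect_false(identical(a$entries, c$entries))
})

test_that("a degenerate single-profile config emits exactly that profile", {
  universe <- tibble::tibble(drug = c("a", "b"),
                             atc_code = c("C07AB07", "J01CA04"))
  cfg <- sim_config(n_reports = 50, drug_universe = universe,
                    profiles = list(therapy_profile("only", c("a", "b"),
                                                    1, 1)),
                    background_rate = 0, seed = 2)
  sim <- simulate_icsr(cfg)
  sets <- split(sim$entries$drug, sim$entries$report_id)
  expect_true(all(vapply(sets, function(s)
    identical(sort(s), c("a", "b")), TRUE)))
})

test_that("invalid configurations are rejected", {
  universe <- tibble::tibble(drug = c("a", "b"), atc_code = c("C07AB07",
                                                              "J01CA04"))
  expect_error(sim_config(10, universe, background_rate = 1.4), "probabilities")
  expect_error(sim_config(10, universe,
                          profiles = list(therapy_profile("p", "zz", 0.5,
                                                          0.5))),
               "outside the universe")
  expect_error(sim_config(10, universe), "at least one profile")
})

test_that("marginal prevalence converges to the activation x inclusion product", {
  # one profile {a,b}, activation .6, inclusion .5/.9, background .01; with
  # redraw-to-nonempty the retained-at->=1-drug marginal is the unconditional
  # rate divided by P(report nonempty)
  universe <- tibble::tibble(drug = c("a", "b", "c"),
                             atc_code = c("C07AB07", "J01CA04", "N02BE01"))
  act <- 0.6; inc <- c(0.5, 0.9); bg <- 0.01
  cfg <- sim_config(n_reports = 50000, drug_universe = universe,
                    profiles = list(therapy_profile("p", c("a", "b"), inc,
                                                    act)),
                    background_rate = bg, seed = 4)
  sim <- simulate_icsr(cfg)
  p_in <- function(q) 1 - (1 - act * q) * (1 - bg)  # profile OR background
  p_nonempty <- 1 - (1 - act * (1 - prod(1 - inc))) * (1 - bg)^3
  for (i in 1:2) {
    target <- p_in(inc[i]) / p_nonempty
    # a drug can also enter via background when the profile is active but the
    # inclusion draw failed; p_in covers that via the OR
    obs <- mean(vapply(split(sim$entries$drug, sim$entries$report_id),
                       function(s) c("a", "b")[i] %in% s, TRUE))
    se <- sqrt(target * (1 - target) / cfg$n_reports)
    expect_lt(abs(obs - target), 3 * se + 0.003)
  }
})

test_that("disjoint single-activation profiles produce no cross-profile pairs", {
  universe <- tibble::tibble(drug = sprintf("d%02d", 1:10),
                             atc_code = sprintf("C01AA%02d", 1:10))
  cfg <- sim_config(
    n_reports = 2000, drug_universe = universe,
    profiles = list(
      therapy_profile("p1", sprintf("d%02d", 1:5), 0.9, 0.15),
      therapy_profile("p2", sprintf("d%02d", 6:10), 0.9, 0.15)),
    background_rate = 0, seed = 6)
  sim <- simulate_icsr(cfg)
  act <- sim$truth$report_profiles
  single <- rownames(act)[rowSums(act) == 1]
  x <- report_set(dplyr::distinct(
    sim$entries[sim$entries$report_id %in% single, c("report_id", "drug")]))
  pairs <- count_ksets(x, 2)
  lab <- setNames(sim$truth$drug_labels$profile, sim$truth$drug_labels$drug)
  expect_true(all(lab[pairs$drug1] == lab[pairs$drug2]))
})

test_that("filters recover the noise-free cohort when noise marks are honored", {
  cfg <- default_agep_config(n_reports = 600, seed = 12)
  clean_cfg <- cfg
  clean_cfg$noise <- list(duplicate_fraction = 0, unknown_name_fraction = 0)
  noisy <- simulate_icsr(cfg)
  # honor the marks: restore tokenized names, drop flagged duplicates
  entries <- noisy$entries
  restore <- setNames(noisy$truth$unknown_map$drug,
                      noisy$truth$unknown_map$token)
  hit <- entries$drug %in% names(restore)
  entries$drug[hit] <- restore[entries$drug[hit]]
  x_noisy <- apply_exclusions(entries, noisy$meta, atc_table(cfg))
  keep <- !noisy$meta$duplicate_flag
  x_clean <- apply_exclusions(noisy$entries[noisy$entries$report_id %in%
                                              noisy$meta$report_id[keep], ] |>
                                dplyr::mutate(drug = ifelse(drug %in%
                                  names(restore), restore[drug], drug)),
                              noisy$meta[keep, ], atc_table(cfg))
  expect_equal(x_noisy$drugs, x_clean$drugs)
  expect_equal(x_noisy$flow[["retained"]], x_clean$flow[["retained"]])
})

test_that("the default cohort matches the headline demographic structure", {
  cfg <- default_agep_config(seed = 1)
  sim <- simulate_icsr(cfg)
  x <- apply_exclusions(sim$entries, sim$meta, atc_table(cfg))
  nd <- as.integer(table(x$drugs$report_id))
  expect_equal(stats::median(nd), 3)
  expect_lt(abs(mean(x$meta$sex == "female") - 0.593), 0.02)
  expect_lt(abs(mean(x$meta$death, na.rm = TRUE) - 0.025), 0.01)
  expect_lt(abs(mean(x$meta$age_years, na.rm = TRUE) - 57.3), 1.5)
  expect_gt(mean(x$meta$serious, na.rm = TRUE), 0.89)
  # cascade shape: ~5983 extracted -> ~2649 retained
  expect_equal(x$flow[["extracted"]], 5983L)
  expect_lt(abs(x$flow[["retained"]] - 2649) / 2649, 0.05)
})
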
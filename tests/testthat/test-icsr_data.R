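test_that("parsing a small table yields normalized entries and report metadata", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_icsr(path, c(
    "report_id\tdrug_name\trole\tage_years\tsex",
    "r1\t Amoxicillin \tsuspected\t34\tfemale",
    "r1\tParacetamol\tconcomitant\t34\tfemale",
    "r2\tBISOPROLOL\tsuspected\t71\tmale"
  ))
  parsed <- read_icsr_table(path)
  expect_equal(nrow(parsed$entries), 3)
  expect_equal(dplyr::n_distinct(parsed$entries$report_id), 2)
  expect_equal(parsed$entries$drug,
               c("amoxicillin", "paracetamol", "bisoprolol"))
  expect_equal(parsed$meta$sex, c("female", "male"))
  expect_equal(parsed$n_rejected, 0)
})

test_that("rows with empty drug names are rejected and counted", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_icsr(path, c(
    "report_id\tdrug_name",
    "r1\tamoxicillin",
    "r1\t   ",
    "r2\tibuprofen"
  ))
  parsed <- read_icsr_table(path)
  expect_equal(nrow(parsed$entries), 2)
  expect_equal(parsed$n_rejected, 1)
})

test_that("a missing required column is a configuration error naming it", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_icsr(path, c("report_id\tmedicine", "r1\tamoxicillin"))
  expect_error(read_icsr_table(path), "drug_name")
  expect_no_error(read_icsr_table(path, icsr_dialect(drug = "medicine")))
})

test_that("ATC map validates code syntax and accepts level prefixes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_icsr(path, c("drug\tatc", "bisoprolol\tC07AB07",
                          "aspirin\tB01AC", "insulin\tA10"))
  map <- read_atc_map(path)
  expect_equal(nrow(map), 3)
  write_tiny_icsr(path, c("drug\tatc", "bad\tX9"))
  expect_error(read_atc_map(path), "invalid ATC")
})

test_that("assign_atc sets atc1 to the code's first character and flags unmapped", {
  map <- tibble::tibble(drug = c("bisoprolol", "amoxicillin"),
                        atc_code = c("C07AB07", "J01CA04"))
  entries <- tibble::tibble(report_id = "r1",
                            drug = c("bisoprolol", "mystery compound"))
  out <- assign_atc(entries, map)
  expect_equal(out$atc1[1], "C")
  expect_true(is.na(out$atc_code[2]))
})

test_that("an ingredient with two mapped codes gets the smallest code, with warning", {
  map <- tibble::tibble(drug = c("aspirin", "aspirin"),
                        atc_code = c("N02BA01", "B01AC06"))
  entries <- tibble::tibble(report_id = "r1", drug = "aspirin")
  expect_warning(out <- assign_atc(entries, map), "aspirin")
  expect_equal(out$atc_code, "B01AC06")  # B... < N... lexicographically
})

test_that("exclusion cascade drops duplicates, unmapped drugs, and <2-drug reports", {
  map <- tibble::tibble(drug = c("a", "b", "c"),
                        atc_code = c("C07AB07", "J01CA04", "N02BE01"))
  entries <- tibble::tibble(
    report_id = c("r1", "r1", "r2", "r2", "r3", "r4", "r4", "r5", "r5"),
    drug = c("a", "b", "a", "a", "c", "a", "zz", "b", "c")
  )
  meta <- tibble::tibble(report_id = paste0("r", 1:5),
                         duplicate_flag = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  x <- apply_exclusions(entries, meta, map)
  # r2 collapses {a,a} to one drug; r3 single drug; r4 keeps only mapped 'a';
  # r5 duplicate-flagged: only r1 survives
  expect_equal(sort(unique(x$drugs$report_id)), "r1")
  expect_equal(unname(x$flow),
               c(extracted = 5L, unique = 4L, with_mapped_drug = 4L,
                 retained = 1L) |> unname())
  expect_true(all(table(x$drugs$report_id) >= 2))
  expect_false(anyNA(x$drugs$atc_code))
})

test_that("cascade counters are non-increasing and account for all exclusions", {
  cfg <- default_agep_config(n_reports = 800, seed = 5)
  sim <- simulate_icsr(cfg)
  x <- apply_exclusions(sim$entries, sim$meta, atc_table(cfg))
  ft <- flow_table(x)
  expect_true(all(diff(ft$n_reports) <= 0))
  expect_equal(sum(ft$excluded), ft$n_reports[1] - ft$n_reports[4])
})

test_that("the exclusion cascade is idempotent", {
  cfg <- default_agep_config(n_reports = 500, seed = 3)
  sim <- simulate_icsr(cfg)
  atc <- atc_table(cfg)
  x1 <- apply_exclusions(sim$entries, sim$meta, atc)
  x2 <- apply_exclusions(x1$drugs, x1$meta, atc)
  expect_equal(x2$drugs, x1$drugs)
  expect_equal(x2$flow[["extracted"]], x2$flow[["retained"]])
})

test_that("synthetic output round-trips through the table dialect", {
  cfg <- default_agep_config(n_reports = 300, seed = 9)
  sim <- simulate_icsr(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_icsr_table(sim$entries, sim$meta, path)
  parsed <- read_icsr_table(path)
  atc <- atc_table(cfg)
  x1 <- apply_exclusions(sim$entries, sim$meta, atc)
  x2 <- apply_exclusions(parsed$entries, parsed$meta, atc)
  expect_equal(x2$flow, x1$flow)
  expect_equal(dplyr::arrange(x2$drugs, report_id, drug),
               dplyr::arrange(x1$drugs, report_id, drug))
  expect_equal(x2$meta$sex, x1$meta$sex)
  expect_equal(x2$meta$age_years, x1$meta$age_years)
})

test_that("age groups follow the table bands and age consistency is enforced", {
  expect_equal(age_group_of(c(3, 16, 44.9, 45, 64, 65, 84, 85, NA)),
               c("<16", "16-44", "16-44", "45-64", "45-64", "65-84", "65-84",
                 "85+", "unknown"))
  expect_error(
    report_set(tibble::tibble(report_id = "r1", drug = c("a", "b")),
               meta = tibble::tibble(report_id = "r1", age_years = 30,
                                     age_group = "85+")),
    "inconsistent")
})
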
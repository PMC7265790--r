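# Edition assignment, survival discretization, stage grouping, and the
# rule-based 7th-to-6th edition reclassifier.

test_that("edition assignment follows the year mapping and rejects unmapped years", {
  expect_identical(assign_edition(2016), "7")
  expect_identical(assign_edition(1999), "5")
  expect_identical(assign_edition(c(2003, 2009, 2010)), c("6", "6", "7"))
  expect_error(assign_edition(1985), "outside the edition mapping")
  custom <- data.frame(from = 1990, to = 1995, edition = "5")
  expect_identical(assign_edition(1991, custom), "5")
})

test_that("survival discretization has five categories and the censoring rule", {
  cats <- survival_categories()
  expect_length(cats, 5L)
  expect_identical(cats[5], ">=24mo")
  # alive with < 2 years of follow-up is right-censored below the top bound
  expect_true(is.na(discretize_survival(400, "alive")))
  expect_identical(discretize_survival(900, "alive"), cats[5])
  # 100 days ~ 3.3 months under the 30.44 days/month convention
  expect_identical(discretize_survival(100, "dead"), "3-<6mo")
  expect_identical(discretize_survival(0, "dead"), "0-<3mo")
  expect_identical(discretize_survival(800, "dead"), ">=24mo")
  expect_error(discretize_survival(-1, "dead"), "non-negative")
  expect_error(discretize_survival(10, "lost"), "vital_status")
  # boundary day arithmetic: 731 days is the first day of the top category
  expect_identical(discretize_survival(731, "alive"), cats[5])
  expect_true(is.na(discretize_survival(730, "alive")))
})

test_that("stage grouping reproduces the worked examples", {
  # distant metastases always dominate
  expect_identical(stage_group("T3", "N1", "M1", "6"), "IV")
  expect_identical(stage_group("T1a", "N0", "M1b", "7"), "IV")
  # N2 with M0: any T2 or T3 yields IIIA
  expect_identical(stage_group("T2", "N2", "M0", "6"), "IIIA")
  expect_identical(stage_group("T3", "N2", "M0", "6"), "IIIA")
  expect_identical(stage_group("T1", "N0", "M0", "6"), "IA")
  # stage computable without the T descriptor when all candidates agree
  expect_identical(stage_group("TX", "N3", "M0", "6"), "IIIB")
  # but not when candidates disagree
  expect_identical(stage_group("TX", "NX", "M0", "7"), "UNKNOWN")
  expect_identical(stage_group("T0", "N0", "M0", "6"), "UNKNOWN")
  expect_error(stage_group("T2a", "N0", "M0", "6"), "not a valid T token")
  expect_error(stage_group("T1", "N0", "M1", "7"), "not a valid M token")
})

test_that("stage grouping is total and pure over every valid combination", {
  for (ed in c("5", "6", "7")) {
    voc <- tnm_vocabulary(ed)
    grid <- expand.grid(t = voc$t, n = voc$n, m = voc$m, stringsAsFactors = FALSE)
    s1 <- stage_group(grid$t, grid$n, grid$m, ed)
    s2 <- stage_group(grid$t, grid$n, grid$m, ed)
    expect_identical(s1, s2)
    expect_true(all(s1 %in% c(stage_levels(), "UNKNOWN")))
    # M1 dominance over the whole vocabulary
    meta <- grid$m %in% c("M1", "M1a", "M1b")
    expect_true(all(s1[meta] == "IV"))
    # definite triples always resolve to a stage
    def <- tnmbn:::definite_tokens(ed)
    dgrid <- expand.grid(t = def$t, n = def$n, m = def$m, stringsAsFactors = FALSE)
    expect_false(any(stage_group(dgrid$t, dgrid$n, dgrid$m, ed) == "UNKNOWN"))
  }
})

test_that("editions 5 and 6 share one grouping table", {
  def <- tnmbn:::definite_tokens("6")
  grid <- expand.grid(t = def$t, n = def$n, m = def$m, stringsAsFactors = FALSE)
  expect_identical(stage_group(grid$t, grid$n, grid$m, "5"),
                   stage_group(grid$t, grid$n, grid$m, "6"))
})

test_that("rule reclassifier maps descriptors with the documented ambiguities", {
  # nonmetastatic multifocal T4: neither the 6th-edition T nor M determinable
  r <- rule_reclassify_7to6(data.frame(t = "T4", n = "N0", m = "M0",
                                       multifocal = TRUE))
  expect_true(all(c("M0", "M1") %in% strsplit(r$m_range, "|", fixed = TRUE)[[1]]))
  expect_false(r$definitive)
  # T3 with unknown invasion status: T2 or T3
  r <- rule_reclassify_7to6(data.frame(t = "T3", n = "N0", m = "M0",
                                       multifocal = FALSE))
  expect_identical(r$t_range, "T2|T3")
  # size subdivision collapses to the parent category
  r <- rule_reclassify_7to6(data.frame(t = "T1a", n = "N0", m = "M0",
                                       multifocal = FALSE))
  expect_identical(r$t_range, "T1")
  expect_identical(r$stage_range, "IA")
  expect_true(r$definitive)
  # N maps identically in all patients
  r <- rule_reclassify_7to6(data.frame(t = c("T1b", "T3", "T4"),
                                       n = c("N3", "N1", "N2"),
                                       m = c("M0", "M0", "M1b")))
  expect_identical(r$n, c("N3", "N1", "N2"))
  # metastatic M short-circuits to IV no matter how ambiguous T is
  expect_identical(r$stage_range[3], "IV")
  expect_error(rule_reclassify_7to6(data.frame(t = "T2", n = "N0", m = "M0",
                                               edition = "6")),
               "7th-edition")
})

test_that("missing extras widen ranges instead of erroring", {
  r_known <- rule_reclassify_7to6(data.frame(t = "T3", n = "N0", m = "M0",
                                             multifocal = FALSE))
  r_missing <- rule_reclassify_7to6(data.frame(t = "T3", n = "N0", m = "M0"))
  t_known <- strsplit(r_known$t_range, "|", fixed = TRUE)[[1]]
  t_missing <- strsplit(r_missing$t_range, "|", fixed = TRUE)[[1]]
  expect_true(all(t_known %in% t_missing))
  expect_gt(length(t_missing), length(t_known))
})

test_that("stage ranges equal the brute-force product over descriptor candidates", {
  set.seed(7)
  voc <- tnmbn:::definite_tokens("7")
  cases <- expand.grid(t = voc$t, n = voc$n, m = voc$m,
                       mf = c(TRUE, FALSE, NA), stringsAsFactors = FALSE)
  cases <- cases[sample(nrow(cases), 60), ]
  for (i in seq_len(nrow(cases))) {
    rec <- data.frame(t = cases$t[i], n = cases$n[i], m = cases$m[i],
                      multifocal = cases$mf[i])
    r <- rule_reclassify_7to6(rec)
    t_range <- strsplit(r$t_range, "|", fixed = TRUE)[[1]]
    m_range <- strsplit(r$m_range, "|", fixed = TRUE)[[1]]
    oracle <- sort(unique(unlist(
      lapply(t_range, function(tt) lapply(m_range, function(mm)
        stage_group(tt, r$n, mm, "6")))
    )))
    oracle <- setdiff(oracle, "UNKNOWN")
    got <- sort(strsplit(r$stage_range, "|", fixed = TRUE)[[1]])
    expect_identical(got, oracle)
    expect_gte(length(got), 1L)
  }
})

test_that("two-candidate stage ranges take the forms the rule table produces", {
  cfg <- simulation_config(n_records = 4000, years = 2015:2016, seed = 99)
  sim <- simulate_registry(cfg)
  rr <- rule_reclassify_7to6(sim$records)
  two <- rr$stage_range[lengths(strsplit(rr$stage_range, "|", fixed = TRUE)) == 2]
  expect_gt(length(two), 0)
  # {T2,T3} ambiguity classes: IB|IIB (N0 M0) and IIB|IIIA (N1 M0)
  expect_true(all(unique(two) %in% c("IB|IIB", "IIB|IIIA", "IIIA|IIIB", "IIIB|IV")))
  # the N2 M0 shortcut resolves {T2,T3} to a definitive IIIA
  n2 <- sim$records$n == "N2" & sim$records$m == "M0" & sim$records$t == "T3" &
    !is.na(sim$records$multifocal) & !sim$records$multifocal
  expect_true(all(rr$definitive[n2]))
  expect_true(all(rr$stage[n2] == "IIIA"))
})

test_that("registry CSV round trip preserves records and derives fields", {
  cfg <- simulation_config(n_records = 300, seed = 12)
  sim <- simulate_registry(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(sim$records, path)
  back <- read_registry(path)
  for (col in c("incidence_year", "edition", "t", "n", "m", "stage",
                "follow_up_days", "vital_status", "survival")) {
    expect_identical(back[[col]], sim$records[[col]], label = col)
  }
  # edition derived from year when the column is absent
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw$edition <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw, path2, row.names = FALSE, na = "")
  back2 <- read_registry(path2)
  expect_identical(back2$edition, sim$records$edition)
  expect_error(read_registry(path2, mapping = data.frame(from = 2010, to = 2016,
                                                         edition = "7")),
               "outside the edition mapping")
})
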
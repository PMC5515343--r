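test_that("any-defect integration matches the rule over the full grid", {
  meths <- c("occult_tumor", "field_effect", "normal", NA)
  cns <- c("evidence_of_tumor", "small_evidence", "likely_evidence",
           "normal", NA)
  exomes <- c("high", "moderate", "low", "none", NA)
  rnas <- c(TRUE, FALSE)
  grid <- expand.grid(meth = meths, cn = cns, exome = exomes, rna = rnas,
                      stringsAsFactors = FALSE)
  suppressMessages(
    got <- integrate_defects(sprintf("P%03d", seq_len(nrow(grid))),
                             grid$meth, grid$cn, grid$exome, grid$rna))
  want <- apply(grid, 1, function(g) {
    hits <- c(identical(g[["meth"]], "occult_tumor"),
              g[["cn"]] %in% c("evidence_of_tumor", "likely_evidence"),
              g[["exome"]] %in% c("moderate", "high"))
    if (is.na(g[["meth"]]) && is.na(g[["cn"]]) && is.na(g[["exome"]])) NA
    else any(hits, na.rm = TRUE)
  })
  expect_equal(got$any_defect, unname(want))
  # RNA positivity never contributes
  expect_false(any(got$any_defect[grid$meth %in% "normal" &
                                    grid$cn %in% "normal" &
                                    grid$exome %in% "none"], na.rm = TRUE))
})

test_that("worked integration examples", {
  d <- suppressMessages(integrate_defects(
    c("A", "B", "C"),
    methylation_category = c("normal", "field_effect", NA),
    cn_category = c("normal", "small_evidence", NA),
    exome_category = c("high", "low", NA),
    rna_positive = c(FALSE, TRUE, NA)))
  expect_equal(d$any_defect, c(TRUE, FALSE, NA))
  expect_equal(d$n_platforms, c(3, 3, 0))
})

test_that("KM equals 1 - ECDF without censoring and applies the 10y cut", {
  times <- c(1, 2, 2, 3.5, 5, 7, 8, 9)
  rec <- small_clinical(8, time = times, event = TRUE)
  km <- km_fit(rec, rep("all", 8), censor_at = Inf)
  ecdf_t <- ecdf(times)
  for (i in seq_len(nrow(km$curves)))
    expect_equal(km$curves$survival[i], 1 - ecdf_t(km$curves$time[i]),
                 tolerance = 1e-12)

  # an event at 12y is censored at the 10-year horizon
  rec2 <- small_clinical(4, time = c(2, 5, 12, 14), event = TRUE)
  km2 <- km_fit(rec2, rep("all", 4), censor_at = 10)
  expect_equal(max(km2$curves$time), 10)
  expect_equal(sum(km2$curves$n_event), 2)
  expect_equal(min(km2$curves$survival), 0.5)

  expect_error(km_fit(rec2, c("a", "a", NA, "a")), "group")
  rec0 <- small_clinical(3, time = 1, event = FALSE)
  expect_error(km_fit(rec0, rep("a", 3)), "no events")
})

test_that("Cox fit recovers a binary effect and guards degeneracy", {
  set.seed(40)
  n <- 400
  x <- rep(c("inactive", "active"), each = n / 2)
  d <- small_clinical(n, time = 1, event = TRUE)
  d$subtype <- x
  d$time_years <- rexp(n, 0.05 * exp(log(3) * (x == "active")))
  d$event <- d$time_years <= 10
  d$time_years <- pmin(d$time_years, 10)
  fit <- cox_fit(d, covariates = "subtype")
  hr <- fit$terms$hazard_ratio[fit$terms$term == "subtypeactive"]
  expect_gt(hr, 2.2); expect_lt(hr, 4.0)
  expect_true(fit$terms$ci_low[1] < hr && hr < fit$terms$ci_high[1])

  d0 <- d; d0$event <- FALSE
  expect_error(cox_fit(d0, covariates = "subtype"), "no events")
})

test_that("reference levels put inactive / negative / stage I at baseline", {
  set.seed(41)
  d <- small_clinical(60, time = rexp(60, 0.2), event = TRUE)
  d$subtype <- rep(c("active", "inactive"), 30)
  # decouple covariates (period-4 patterns) to avoid collinearity
  d$node_status <- factor(rep(c("negative", "negative", "positive",
                                "positive"), 15),
                          levels = c("negative", "positive"))
  d$stage <- factor(rep(c("I", "II", "II", "I"), 15),
                    levels = c("I", "II", "III/IV"))
  fit <- cox_fit(d, covariates = c("subtype", "node_status", "stage"))
  expect_true(all(c("subtypeactive", "node_statuspositive", "stageII") %in%
                    fit$terms$term))
  expect_false(any(grepl("inactive|negative|stageI$", fit$terms$term)))
  # constant covariates are dropped with a message rather than breaking the fit
  d$t_size <- factor("T1", levels = paste0("T", 1:4))
  expect_message(fit2 <- cox_fit(d, covariates = c("subtype", "t_size")),
                 "constant covariate")
  expect_false(any(grepl("t_size", fit2$terms$term)))
})

test_that("stage-IV sensitivity refit equals a manual refit", {
  set.seed(42)
  d <- small_clinical(80, time = rexp(80, 0.15), event = TRUE,
                      stage = c(rep("I", 40), rep("III/IV", 40)),
                      stage_raw = c(rep("I", 40), rep("III", 30),
                                    rep("IV", 10)))
  d$subtype <- rep(c("active", "inactive"), 40)
  out <- sensitivity_exclude_stage(d, covariates = "subtype")
  expect_equal(out$n_removed, 10)
  manual <- cox_fit(d[d$stage_raw != "IV", ], covariates = "subtype")
  expect_equal(out$filtered$terms, manual$terms, tolerance = 1e-12)

  none <- sensitivity_exclude_stage(d[d$stage_raw != "IV", ],
                                    covariates = "subtype")
  expect_equal(none$n_removed, 0)
  expect_identical(none$filtered$terms, none$primary$terms)
})

test_that("association battery picks tests by expected counts", {
  d <- small_clinical(80, time = 1, event = FALSE)
  sub <- rep(c("active", "inactive"), 40)
  # perfectly balanced 2x2 -> chi-square 0, p = 1
  d$node_status <- factor(rep(c("negative", "positive", "positive",
                                "negative"), 20),
                          levels = c("negative", "positive"))
  # both subtypes see both age decades equally -> pooled t statistic 0
  d$age_decade <- factor(rep(c("40-49", "50-59", "50-59", "40-49"), 20),
                         levels = levels(d$age_decade))
  tab <- association_tests(d, sub)
  node <- tab[tab$variable == "node_status", ]
  expect_equal(node$test, "chi-square")
  expect_equal(node$statistic, 0, tolerance = 1e-12)
  expect_equal(node$p_value, 1, tolerance = 1e-12)
  # equal-mean ages -> t ~ 0
  age <- tab[tab$variable == "age", ]
  expect_equal(age$test, "pooled t-test")
  expect_lt(abs(age$statistic), 1e-12)

  # sparse 2x2 (expected counts < 5) falls back to Fisher, exact oracle
  d2 <- small_clinical(20, time = 1, event = FALSE)
  sub2 <- rep(c("active", "inactive"), each = 10)
  d2$any_defect <- c(rep(TRUE, 3), rep(FALSE, 7), rep(FALSE, 10))
  t2 <- association_tests(d2, sub2)
  fish <- t2[t2$variable == "any_defect", ]
  expect_equal(fish$test, "fisher")
  expect_equal(fish$p_value,
               fisher.test(table(sub2, d2$any_defect))$p.value,
               tolerance = 1e-12)
  expect_equal(fish$p_value, oracle_fisher(7, 3, 10, 0), tolerance = 1e-12)
})

test_that("written cohorts reload into the pipeline's input shape", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_patients = 5, n_probes = 1200, n_somatic_snvs = 4,
                    n_mrna_features = 40, n_mir_features = 40, seed = 66)
  co <- simulate_cohort(cfg, out_dir = dir)
  back <- read_cohort(dir)
  expect_equal(unclass(back$methylation$adjacent),
               unclass(co$methylation$adjacent), tolerance = 1e-12)
  expect_equal(back$segments[["P002"]]$tumor$start,
               co$segments[["P002"]]$tumor$start)
  expect_equal(back$variants$n_alt, co$variants$n_alt)
  expect_equal(as.data.frame(back$expression$clinical)$time_years,
               co$expression$clinical$time_years, tolerance = 1e-12)
  expect_equal(back$truth$occult_fraction, co$truth$occult_fraction,
               tolerance = 1e-12)
})

test_that("the end-to-end pipeline report carries every stage", {
  cfg <- sim_config(n_patients = 40, n_probes = 1200, n_mrna_features = 300,
                    n_mir_features = 300, seed = 55)
  co <- simulate_cohort(cfg)
  rep <- suppressWarnings(run_pipeline(co, runs_survey = 3, runs_final = 20,
                                       n_perms = 200, seed = 55))
  expect_s3_class(rep, "fieldscape_report")
  expect_equal(nrow(rep$methylation), 40)
  expect_equal(nrow(rep$defects), 40)
  expect_true(rep$concordance >= 0.5 && rep$concordance <= 1)
  expect_true(all(c("subtypeactive") %in% rep$cox$terms$term))
  # defect integration agrees with recomputing from the stage tables
  m <- rep$methylation$category[match(rep$defects$patient_id,
                                      rep$methylation$sample_id)]
  expect_equal(rep$defects$any_defect,
               m == "occult_tumor" |
                 rep$defects$cn_category %in%
                 c("evidence_of_tumor", "likely_evidence") |
                 rep$defects$exome_category %in% c("moderate", "high"))
})
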
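# Generator contracts: determinism, empty cases, rate calibration against
# closed-form Poisson / competing-exponential expectations.

test_that("sim_config validates its inputs", {
  expect_error(sim_config(n_families = -1), "non-negative")
  expect_error(sim_config(study_start = "2000-01-01", study_end = "1999-01-01"),
               "study_end")
  expect_error(sim_config(category_diagnosis_rates = c(Bogus = 0.1)),
               "unknown category")
  expect_error(sim_config(true_log_rr = c(Hypertension = Inf)), "finite")
  expect_error(sim_config(baseline_abuse_hazard = -1), "non-negative")
})

test_that("generate_population: empty case and determinism", {
  empty <- generate_population(sim_config(n_families = 0))
  expect_equal(nrow(empty$persons), 0)

  cfg <- sim_config(n_families = 50, seed = 7)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  for (tab in c("persons", "links", "families", "covariates"))
    expect_identical(as.data.frame(a[[tab]]), as.data.frame(b[[tab]]))
  # every child has at least one linked parent
  ch <- a$persons$person_id[a$persons$role == "child"]
  expect_true(all(ch %in% a$links$child_id))
  np <- table(a$links$child_id)
  expect_true(all(np >= 1 & np <= 2))
})

test_that("family-size distribution matches the configured law", {
  cfg <- sim_config(n_families = 1000, seed = 3)
  snap <- generate_population(cfg)
  p2plus <- 1 - cfg$covariate_distributions$n_children_p[1]
  obs <- mean(snap$families$n_children >= 2)
  tol <- 3 * sqrt(p2plus * (1 - p2plus) / 1000)
  expect_lt(abs(obs - p2plus), tol)
})

test_that("health events: zero rates, Poisson mean, and the read-in bound", {
  zero <- sim_config(n_families = 20, seed = 1)
  zero$category_diagnosis_rates[] <- 0
  zero$prescription_rates[] <- 0
  ev <- generate_health_events(generate_population(zero), zero)
  expect_equal(nrow(ev$diagnoses), 0)
  expect_equal(nrow(ev$prescriptions), 0)

  cfg <- sim_config(n_families = 400, seed = 5)
  cfg$category_diagnosis_rates[] <- 0
  cfg$category_diagnosis_rates["Hypertension"] <- 0.1
  cfg$prescription_rates[] <- 0
  snap <- generate_population(cfg)
  ev <- generate_health_events(snap, cfg)
  n_parents <- sum(snap$persons$role == "parent")
  T_years <- as.numeric(cfg$study_end -
                          add_months(cfg$study_start, -36L)) / 365.25
  lambda <- 0.1 * T_years
  mean_per_parent <- nrow(ev$diagnoses) / n_parents
  tol <- 3 * sqrt(lambda / n_parents)
  expect_lt(abs(mean_per_parent - lambda), tol)
  # no event before the read-in start, none after study end
  expect_true(all(ev$diagnoses$date >= add_months(cfg$study_start, -36L)))
  expect_true(all(ev$diagnoses$date <= cfg$study_end))
})

test_that("unknown rate keys are a configuration error", {
  expect_error(sim_config(prescription_rates = c(XX99 = 1)), "unknown ATC")
})

test_that("outcomes: one terminal record per child, ordering invariants", {
  cfg <- sim_config(n_families = 300, seed = 9)
  snap <- simulate_registry(cfg)
  out <- snap$outcomes
  kids <- snap$persons[snap$persons$role == "child", ]
  in_window <- kids$birth_date < cfg$study_end &
    add_months(kids$birth_date, 216L) > cfg$study_start
  expect_equal(sort(out$child_id), sort(kids$person_id[in_window]))
  expect_false(anyDuplicated(out$child_id) > 0)
  expect_true(all(out$type %in% c("abuse", "death", "emigration",
                                  "age18", "study_end")))
  b <- kids$birth_date[match(out$child_id, kids$person_id)]
  expect_true(all(out$date >= b))
  expect_true(all(out$date <= cfg$study_end))
})

test_that("competing exponential race: abuse fraction a/(a+d)", {
  # equal abuse and death hazards, no emigration: among children whose race
  # ends in an event, the abuse share is a/(a+d) = 1/2 in closed form
  cfg <- sim_config(n_families = 1500, seed = 13,
                    baseline_abuse_hazard = 0.02, death_hazard = 0.02,
                    censoring_hazards_by_period = c(0, 0, 0))
  snap <- simulate_registry(cfg)
  tt <- table(snap$outcomes$type)
  n_ev <- tt[["abuse"]] + tt[["death"]]
  frac <- tt[["abuse"]] / n_ev
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_ev))
})

test_that("overwhelming abuse hazard leaves no other first event", {
  cfg <- sim_config(n_families = 60, seed = 2, baseline_abuse_hazard = 200,
                    death_hazard = 0, censoring_hazards_by_period = c(0, 0, 0))
  snap <- simulate_registry(cfg)
  expect_true(all(snap$outcomes$type == "abuse"))
})

test_that("a child born after study end gets no outcome record", {
  cfg <- sim_config(n_families = 30, seed = 4)
  snap <- generate_population(cfg)
  late <- snap$persons$role == "child"
  snap$persons$birth_date[which(late)[1]] <- cfg$study_end + 100
  ev <- generate_health_events(snap, cfg)
  tl <- build_exposure_timeline(cfg$taxonomy, ev$diagnoses, ev$prescriptions,
                                snap$links, cfg$study_start, cfg$study_end)
  out <- generate_outcomes(snap, tl, cfg)
  expect_false(snap$persons$person_id[which(late)[1]] %in% out$child_id)
})

test_that("censoring intensity follows the calendar-time group", {
  cfg <- sim_config(n_families = 2000, seed = 21,
                    baseline_abuse_hazard = 0, death_hazard = 0,
                    censoring_hazards_by_period = c(0.01, 0.05, 0.25))
  snap <- simulate_registry(cfg)
  out <- snap$outcomes
  kids <- snap$persons[snap$persons$role == "child", ]
  b <- pmax(kids$birth_date[match(out$child_id, kids$person_id)],
            cfg$study_start)
  # person-years at risk and emigration counts per calendar period
  bounds <- c(cfg$study_start, cfg$calendar_breaks, cfg$study_end + 1)
  haz <- sapply(1:3, function(p) {
    lo <- bounds[p]; hi <- bounds[p + 1]
    py <- sum(pmax(0, as.numeric(pmin(out$date, hi) - pmax(b, lo)))) / 365.25
    sum(out$type == "emigration" & out$date >= lo & out$date < hi) / py
  })
  # recovered hazards reproduce the configured 1 : 5 : 25 intensity ratios
  expect_equal(haz, cfg$censoring_hazards_by_period, tolerance = 0.15)
  expect_true(haz[1] < haz[2] && haz[2] < haz[3])
})

test_that("true_params reads the config and survives a YAML round-trip", {
  cfg <- sim_config(n_families = 10,
                    true_log_rr = c(Hypertension = log(1.5), Gout = 0))
  tp <- true_params(cfg)
  expect_equal(tp$rr[tp$category == "Hypertension"], 1.5)
  expect_equal(tp$rr[tp$category == "Gout"], 1.0)
  expect_true(all(tp$rr[!tp$category %in% c("Hypertension")] == 1.0))

  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  # yaml serialises doubles at ~9 significant digits
  expect_equal(true_params(cfg2), true_params(cfg), tolerance = 1e-6)
  expect_equal(cfg2$category_diagnosis_rates, cfg$category_diagnosis_rates)
  expect_equal(cfg2$study_start, cfg$study_start)
})
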
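# Matched-cohort construction on small hand-built registries where every
# eligibility decision can be verified by inspection, plus the brute-force
# audit on a simulated registry.

# a family exposed to hypertension from 1998-06 (ever window), several
# candidate control families, constant complete covariates
hand_world <- function(n_ctrl_fams = 8, ctrl_birth = "1999-06-15",
                       ctrl_age = 30, miss_fam = character(0)) {
  cfg <- sim_config(n_families = 1, seed = 1)
  fams <- c("E1", paste0("K", seq_len(n_ctrl_fams)))
  children <- data.table::data.table(
    child_id = paste0("c_", fams), family_id = fams,
    birth_date = as.Date(c("2000-01-01", rep(ctrl_birth, n_ctrl_fams))))
  outcomes <- data.table::data.table(
    child_id = children$child_id, family_id = fams,
    date = as.Date("2015-01-01"), type = "study_end")
  covs <- mini_covariates(fams, 1997:2018, age = ctrl_age)
  for (f in miss_fam) covs$income[covs$family_id == f] <- NA
  snap <- mini_snapshot(children, outcomes, covs, cfg)
  tl <- build_exposure_timeline(
    default_taxonomy(),
    data.frame(person_id = "p_E1", date = as.Date("1998-06-10"), code = "I10"),
    data.frame(person_id = character(), date = as.Date(character()),
               atc_code = character()),
    data.table::data.table(family_id = "E1", parent_id = "p_E1",
                           child_id = "c_E1", link_start = as.Date(NA),
                           link_end = as.Date(NA)),
    cfg$study_start, cfg$study_end)
  tl$families <- fams  # control families carry no events but are known
  list(cfg = cfg, snap = snap, tl = tl, children = children)
}

test_that("index date is the later of exposure onset and birth", {
  w <- hand_world()
  idx <- find_exposed(w$tl, w$children, w$snap$outcomes, "Hypertension", w$cfg)
  expect_equal(nrow(idx), 1L)
  # parent diagnosed 1998, child born 2000 -> index at birth
  expect_equal(idx$index_date, as.Date("2000-01-01"))

  # child born before onset: index at the exposure month start
  w$children$birth_date[1] <- as.Date("1997-03-01")
  w$snap$persons$birth_date[1] <- as.Date("1997-03-01")
  idx2 <- find_exposed(w$tl, w$children, w$snap$outcomes, "Hypertension", w$cfg)
  expect_equal(idx2$index_date, as.Date("1998-07-01"))
})

test_that("children abused before exposure are excluded", {
  w <- hand_world()
  w$snap$outcomes[w$snap$outcomes$child_id == "c_E1",
                  c("date", "type")] <- list(as.Date("1999-06-01"), "abuse")
  idx <- find_exposed(w$tl, w$children, w$snap$outcomes, "Hypertension", w$cfg)
  expect_equal(nrow(idx), 0L)
})

test_that("no exposed families yields an empty, warned cohort", {
  w <- hand_world()
  idx <- find_exposed(w$tl, w$children, w$snap$outcomes, "Gout", w$cfg)
  expect_equal(nrow(idx), 0L)
  expect_warning(sets <- draw_matched_controls(idx, w$snap, w$tl, "Gout"),
                 "no exposed")
  expect_equal(nrow(sets), 0L)
})

test_that("exactly five eligible controls forces a deterministic set", {
  w <- hand_world(n_ctrl_fams = 5)
  idx <- find_exposed(w$tl, w$children, w$snap$outcomes, "Hypertension", w$cfg)
  sets <- draw_matched_controls(idx, w$snap, w$tl, "Hypertension", seed = 1)
  expect_equal(nrow(sets), 6L)
  expect_setequal(sets$child_id[sets$role == "control"],
                  paste0("c_K", 1:5))
})

test_that("fewer than five eligible controls drops the exposed child", {
  w <- hand_world(n_ctrl_fams = 3)
  idx <- find_exposed(w$tl, w$children, w$snap$outcomes, "Hypertension", w$cfg)
  sets <- draw_matched_controls(idx, w$snap, w$tl, "Hypertension", seed = 1)
  expect_equal(nrow(sets), 0L)
  expect_equal(attr(sets, "n_dropped_insufficient"), 1L)
})

test_that("matching filters enforce each window", {
  # birth window: controls born 15 months before the exposed child
  w <- hand_world(n_ctrl_fams = 6, ctrl_birth = "1998-10-01")
  idx <- find_exposed(w$tl, w$children, w$snap$outcomes, "Hypertension", w$cfg)
  sets <- draw_matched_controls(idx, w$snap, w$tl, "Hypertension", seed = 1)
  expect_equal(nrow(sets), 0L)

  # parental age window: controls 7 years older
  w <- hand_world(n_ctrl_fams = 6, ctrl_age = 30)
  w$snap$covariates$mean_parental_age[
    w$snap$covariates$family_id != "E1"] <- 37
  idx <- find_exposed(w$tl, w$children, w$snap$outcomes, "Hypertension", w$cfg)
  sets <- draw_matched_controls(idx, w$snap, w$tl, "Hypertension", seed = 1)
  expect_equal(nrow(sets), 0L)

  # complete-case rule: missing income removes three control families
  w <- hand_world(n_ctrl_fams = 7, miss_fam = c("K1", "K2", "K3"))
  idx <- find_exposed(w$tl, w$children, w$snap$outcomes, "Hypertension", w$cfg)
  sets <- draw_matched_controls(idx, w$snap, w$tl, "Hypertension", seed = 1)
  expect_equal(nrow(sets), 0L)  # only 4 eligible remain

  # exposed child's own covariates incomplete
  w <- hand_world(n_ctrl_fams = 6, miss_fam = "E1")
  idx <- find_exposed(w$tl, w$children, w$snap$outcomes, "Hypertension", w$cfg)
  sets <- draw_matched_controls(idx, w$snap, w$tl, "Hypertension", seed = 1)
  expect_equal(attr(sets, "n_dropped_incomplete"), 1L)
})

test_that("control draws are seeded and satisfy the windows (oracle check)", {
  w <- hand_world(n_ctrl_fams = 20)
  idx <- find_exposed(w$tl, w$children, w$snap$outcomes, "Hypertension", w$cfg)
  s1 <- draw_matched_controls(idx, w$snap, w$tl, "Hypertension", seed = 42)
  s2 <- draw_matched_controls(idx, w$snap, w$tl, "Hypertension", seed = 42)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_length(audit_matched_cohort(s1, w$snap, w$tl, "Hypertension"), 0)
})

test_that("cap_exposed keeps whole sets and is reproducible", {
  sets <- data.table::data.table(
    set_id = rep(1:12, each = 6),
    child_id = sprintf("c%02d", 1:72), family_id = sprintf("f%02d", 1:72),
    role = rep(c("exposed", rep("control", 5)), 12),
    category = "X", index_date = as.Date("2000-01-01"), stratum = "period1")
  expect_identical(cap_exposed(sets, max_n = 100000), sets)
  cap <- cap_exposed(sets, max_n = 10, seed = 5)
  expect_equal(length(unique(cap$set_id)), 10L)
  expect_true(all(table(cap$set_id) == 6))
  expect_identical(as.data.frame(cap_exposed(sets, max_n = 10, seed = 5)),
                   as.data.frame(cap))
})

test_that("follow-up: first-month exclusion, 18-year cap, competing death", {
  w <- hand_world(n_ctrl_fams = 6)
  idx <- find_exposed(w$tl, w$children, w$snap$outcomes, "Hypertension", w$cfg)
  sets <- draw_matched_controls(idx, w$snap, w$tl, "Hypertension", seed = 1)
  expect_equal(nrow(sets), 6L)

  # abuse two weeks after index: inside the excluded first month -> dropped
  snap2 <- w$snap
  snap2$outcomes[snap2$outcomes$child_id == "c_E1",
                 c("date", "type")] <- list(as.Date("2000-01-15"), "abuse")
  fu <- build_followup(sets, snap2)
  expect_false("c_E1" %in% fu$child_id)
  expect_equal(nrow(fu), 5L)  # the set survives

  # abuse after the child turned 18 (cap): censored at the cap, not an event
  snap3 <- w$snap
  snap3$outcomes[snap3$outcomes$child_id == "c_E1",
                 c("date", "type")] <- list(as.Date("2018-06-01"), "abuse")
  fu3 <- build_followup(sets, snap3)
  r <- fu3[fu3$child_id == "c_E1", ]
  expect_equal(r$event, "censored")
  expect_equal(r$exit, 18, tolerance = 0.01)

  # death during follow-up is the competing event
  snap4 <- w$snap
  snap4$outcomes[snap4$outcomes$child_id == "c_K1",
                 c("date", "type")] <- list(as.Date("2004-05-01"), "death")
  fu4 <- build_followup(sets, snap4)
  expect_equal(fu4$event[fu4$child_id == "c_K1"], "death")

  # a cohort child without a terminal record is a data error
  snap5 <- w$snap
  snap5$outcomes <- snap5$outcomes[snap5$outcomes$child_id != "c_K2", ]
  expect_error(build_followup(sets, snap5), "terminal")
})

test_that("simulated-registry cohorts pass the brute-force audit", {
  cfg <- sim_config(n_families = 600, seed = 17)
  snap <- simulate_registry(cfg)
  children <- snap$persons[snap$persons$role == "child", ]
  children <- data.table::data.table(child_id = children$person_id,
                                     family_id = children$family_id,
                                     birth_date = children$birth_date)
  checked <- 0L
  for (cat_name in c("Unspecific symptoms, ever", "Other",
                     "Unspecific symptoms, two years back")) {
    idx <- find_exposed(snap$timeline, children, snap$outcomes, cat_name, cfg)
    sets <- suppressWarnings(draw_matched_controls(
      idx, snap, snap$timeline, cat_name, seed = 17))
    if (nrow(sets) == 0) next
    checked <- checked + length(unique(sets$set_id))
    # ratio invariant and within-cohort uniqueness
    expect_true(all(table(sets$set_id, sets$role)[, "control"] == 5))
    expect_false(anyDuplicated(sets$child_id) > 0)
    expect_length(audit_matched_cohort(sets, snap, snap$timeline, cat_name), 0)
  }
  expect_gt(checked, 0)
})
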
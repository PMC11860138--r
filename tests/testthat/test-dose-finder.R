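test_that("the default escalation grid enumerates 18 regimens", {
  grid <- enumerate_regimens()
  expect_equal(nrow(grid), 18)
  expect_setequal(unique(grid$frequency), c("OD", "BID", "QID"))
  qid2 <- grid[grid$frequency == "QID" & grid$total_daily_mg == 2000, ]
  expect_equal(qid2$dose_mg_per_admin, 500)
  expect_true(all(grid$total_daily_mg <= 10000))
})

test_that("doses beyond the cap are excluded with a warning", {
  expect_warning(grid <- enumerate_regimens(multipliers = c(1, 2, 12)),
                 "exceeds")
  expect_equal(sort(unique(grid$total_daily_mg)), c(1000, 2000))
  expect_error(enumerate_regimens(multipliers = c(-1, 2)), "positive")
})

test_that("extra regimens join the grid without duplication", {
  grid <- enumerate_regimens(extra = list(dose_regimen(1500, "OD", 21),
                                          dose_regimen(1000, "OD", 21)))
  expect_equal(nrow(grid), 19)  # OD 1000 already present
  expect_true("OD_1500" %in% grid$regimen_id)
})

# one shared pipeline run for the decision-rule tests
pipeline <- run_dose_finding(n = 40, seed = 7, grid_step = 0.1)

test_that("the regimen report carries consistent rows and flags", {
  rep <- pipeline$report
  expect_equal(nrow(rep), 19)  # 18-regimen grid + OD 1500 candidate
  expect_true(all(rep$percent_e_mean > 0))
  crit <- pipeline$criteria
  expect_equal(rep$hema_ok_mtd,
               rep$percent_e_mean <= crit$mtd_max_percent_e + 1e-9)
  expect_equal(rep$liver_ok_mtd,
               rep$fold_uln < crit$mtd_max_fold_uln - 1e-9)
  # risk grows monotonically with total daily dose within each frequency
  for (f in c("OD", "BID", "QID")) {
    sub <- rep[rep$frequency == f, ]
    sub <- sub[order(sub$total_daily_mg), ]
    expect_true(all(diff(sub$percent_e_mean) > 0))
  }
})

test_that("FIH selection picks the most divided low-risk schedule", {
  fih <- select_fih(pipeline$report, pipeline$criteria)
  expect_equal(fih$selected$regimen_id, "QID_500")
  expect_equal(fih$selected$total_daily_mg, 2000)
  od_only <- pipeline$report[pipeline$report$frequency == "OD", ]
  fih_od <- select_fih(od_only, pipeline$criteria)
  expect_equal(fih_od$selected$regimen_id, "OD_2000")
  expect_match(fih_od$rationale, "no alternative")
  expect_error(select_fih(pipeline$report[0, ]), "empty")
  no2000 <- pipeline$report[pipeline$report$total_daily_mg != 2000, ]
  expect_error(select_fih(no2000, pipeline$criteria), "FIH total")
})

test_that("MTD selection respects both risk ceilings", {
  mtd <- select_mtd(pipeline$report, pipeline$criteria)
  expect_equal(nrow(mtd$selected), 1)
  expect_lte(mtd$selected$percent_e_mean, 5)
  expect_lt(mtd$selected$fold_uln, 3)
  # nothing qualifying -> empty selection with rationale, not an error
  strict <- decision_criteria(mtd_max_percent_e = 0.001,
                              mtd_max_fold_uln = 0.002,
                              phase2a_max_percent_e = 0.001,
                              phase2a_max_liver_fold = 0.001)
  rep2 <- pipeline$report
  rep2$hema_ok_mtd <- rep2$percent_e_mean <= strict$mtd_max_percent_e
  rep2$liver_ok_mtd <- rep2$fold_uln < strict$mtd_max_fold_uln
  empty <- select_mtd(rep2, strict)
  expect_equal(nrow(empty$selected), 0)
  expect_match(empty$rationale, "no regimen")
  single_row <- pipeline$report[pipeline$report$regimen_id == "QID_250", ]
  expect_equal(select_mtd(single_row,
                          pipeline$criteria)$selected$regimen_id, "QID_250")
})

test_that("phase-2A selection returns OD doses above the efficacy floor", {
  p2a <- select_phase2a(pipeline$report, pipeline$criteria)
  expect_true(all(p2a$selected$frequency == "OD"))
  expect_true(all(p2a$selected$total_daily_mg > 1000))
  expect_true(all(p2a$selected$regimen_id %in% c("OD_1500", "OD_2000")))
  expect_lte(nrow(p2a$selected), 2)
  # an unreachable efficacy floor empties the selection
  high_floor <- decision_criteria(efficacy_floor_daily_mg = 1e6,
                                  max_daily_mg = 2e6, fih_total_daily_mg = 2000)
  expect_equal(nrow(select_phase2a(pipeline$report, high_floor)$selected), 0)
})

test_that("decisions are pure functions of report and criteria", {
  again <- run_dose_finding(n = 40, seed = 7, grid_step = 0.1)
  expect_identical(pipeline$report, again$report)
  expect_identical(select_mtd(pipeline$report, pipeline$criteria)$selected,
                   select_mtd(again$report, again$criteria)$selected)
  # relaxing a threshold never drops a selected regimen
  relaxed <- decision_criteria(mtd_max_percent_e = 10, mtd_max_fold_uln = 6)
  rep3 <- pipeline$report
  rep3$hema_ok_mtd <- rep3$percent_e_mean <= relaxed$mtd_max_percent_e
  rep3$liver_ok_mtd <- rep3$fold_uln < relaxed$mtd_max_fold_uln
  mtd_relaxed <- select_mtd(rep3, relaxed)
  mtd_default <- select_mtd(pipeline$report, pipeline$criteria)
  expect_gte(mtd_relaxed$selected$total_daily_mg,
             mtd_default$selected$total_daily_mg)
})
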
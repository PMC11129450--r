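test_that("observation periods follow the interval/current structure", {
  op <- observation_periods()
  expect_equal(nrow(op), 11)
  expect_equal(op$kind[c(1, 3, 5, 7, 9)], rep("INTERVAL", 5))
  expect_equal(op$kind[c(2, 4, 6, 8, 10, 11)], rep("CURRENT", 6))
})

test_that("index-drug eligibility follows the single-starter rule", {
  expect_equal(eligible_index_ad(tl(`1` = "N06AB05")),
               list(atc = "N06AB05", start_period = 1))
  # started on two drugs at once
  expect_null(eligible_index_ad(tl(`3` = c("N06AB04", "N06AX11"))))
  # never used an antidepressant
  expect_null(eligible_index_ad(medication_timeline(list(), assessed = 1:10)))
  # first use at period 11 only does not qualify
  expect_null(eligible_index_ad(tl(`11` = "N06AB05")))
  # later start with drug-free earlier periods
  expect_equal(eligible_index_ad(tl(`5` = "N06AB06"))$start_period, 5)
  # unassessed earlier periods are skipped, not treated as drug-free
  t <- tl(`4` = "N06AB06", assessed = c(4:11))
  expect_equal(eligible_index_ad(t)$start_period, 4)
})

test_that("comparison pairs prefer gap-spanning comparisons", {
  p <- comparison_pairs(tl(`2` = "A", `3` = "A", `4` = character(0),
                           `5` = character(0), `6` = "B", assessed = 2:6))
  expect_equal(p$earlier, c(2, 3))
  expect_equal(p$later, c(3, 6))
  expect_equal(p$gap_spanning, c(FALSE, TRUE))

  p2 <- comparison_pairs(tl(`1` = "A", `2` = "A", `3` = "A", assessed = 1:3))
  expect_equal(p2$gap_spanning, c(FALSE, FALSE))

  expect_equal(nrow(comparison_pairs(tl(`4` = "A", assessed = 1:11))), 0)

  # unassessed period between two use-periods: pair spans it
  p3 <- comparison_pairs(tl(`2` = "A", `4` = "A", assessed = c(1, 2, 4, 5)))
  expect_equal(nrow(p3), 1)
  expect_true(p3$gap_spanning)
})

test_that("trajectory labels match the definitional scenarios", {
  # maintained throughout
  m <- as.list(setNames(rep("N06AB06", 10), 1:10))
  expect_equal(classify_trajectory(medication_timeline(m, assessed = 1:11)),
               "MAINTAINED")
  # discontinued: use in 1-4 only, later periods assessed and empty
  expect_equal(classify_trajectory(tl(`2` = "N06AB05", `3` = "N06AB05",
                                      `4` = "N06AB05")),
               "DISCONTINUED")
  # switched across a drug-free gap
  expect_equal(classify_trajectory(tl(`2` = "N06AB04", `3` = "N06AB04",
                                      `6` = "N06AB03", `7` = "N06AB03",
                                      `8` = "N06AB03", `9` = "N06AB03",
                                      `10` = "N06AB03")),
               "SWITCHED")
  # use confined to 1-4 with no assessment beyond period 4
  expect_equal(classify_trajectory(tl(`1` = "N06AA09", `2` = "N06AA09",
                                      `3` = "N06AA09", `4` = "N06AA09",
                                      assessed = 1:4)),
               "NOT_CLASSIFIABLE")
  # initiation later in the window counts as maintained
  expect_equal(classify_trajectory(tl(`6` = "N06AB05", `7` = "N06AB05")),
               "MAINTAINED")
  # classification demands an eligible timeline
  expect_error(classify_trajectory(tl(`3` = c("A", "B"))), "eligible")
})

test_that("same-drug restart across a gap is never a switch; a different drug always is", {
  restart <- tl(`1` = "N06AB05", `2` = "N06AB05", `6` = "N06AB05",
                `7` = "N06AB05")
  expect_equal(classify_trajectory(restart), "MAINTAINED")
  for (gap_len in 1:6) {
    m <- list(`1` = "N06AB05")
    m[[as.character(2 + gap_len)]] <- "N06AB04"
    expect_equal(classify_trajectory(medication_timeline(m, assessed = 1:11)),
                 "SWITCHED", info = paste("gap", gap_len))
  }
})

test_that("augmentation (adding a drug while keeping the first) is not a switch", {
  expect_equal(classify_trajectory(tl(`1` = "N06AX16", `2` = "N06AX16",
                                      `5` = c("N06AX16", "N06AX11"),
                                      `6` = c("N06AX16", "N06AX11"))),
               "MAINTAINED")
  # full replacement of the set is a switch
  expect_equal(classify_trajectory(tl(`1` = "N06AX16",
                                      `2` = c("N06AB05", "N06AX11")))
               , "SWITCHED")
})

test_that("widening a drug-free gap never changes the label", {
  base <- classify_trajectory(tl(`2` = "N06AB04", `5` = "N06AB03"))
  for (later in 6:10) {
    m <- list(`2` = "N06AB04")
    m[[as.character(later)]] <- "N06AB03"
    expect_equal(classify_trajectory(medication_timeline(m, assessed = 1:11)),
                 base)
  }
})

test_that("period 11 joins switch comparisons but not maintained eligibility", {
  # switch detected between period 10 and 11
  expect_equal(classify_trajectory(tl(`9` = "N06AB05", `10` = "N06AB05",
                                      `11` = "N06AB04")),
               "SWITCHED")
  # use at period 11 alone does not make a patient eligible
  expect_null(eligible_index_ad(tl(`11` = "N06AB04")))
  # use in 1-4 with drug at period 11 violates the 5-11 emptiness test
  expect_equal(classify_trajectory(tl(`2` = "N06AB05", `11` = "N06AB05")),
               "MAINTAINED")
})

test_that("cohort classification is invariant to input row order", {
  co <- generate_cohort(cohort_config(n_patients = 120), seed = 42)
  tr1 <- classify_cohort(co$medications, co$participation)
  set.seed(99)
  perm <- sample(nrow(co$medications))
  perm2 <- sample(nrow(co$participation))
  tr2 <- classify_cohort(co$medications[perm, ], co$participation[perm2, ])
  tr2 <- tr2[match(tr1$patient_id, tr2$patient_id), ]
  rownames(tr2) <- NULL
  expect_equal(tr1, tr2)
})

test_that("every eligible patient gets exactly one label and counts add up", {
  co <- generate_cohort(cohort_config(n_patients = 300), seed = 5)
  tr <- classify_cohort(co$medications, co$participation)
  expect_equal(sum(tr$eligible), sum(!is.na(tr$label)))
  lbl <- tr$label[tr$eligible]
  expect_true(all(lbl %in% c("MAINTAINED", "SWITCHED", "DISCONTINUED",
                             "NOT_CLASSIFIABLE")))
  expect_equal(length(lbl), sum(table(lbl)))
})

test_that("subsample membership follows the index drug's substrate class", {
  expect_setequal(subsample_membership("N06AB04"), c("CYP2D6", "CYP2C19"))
  expect_equal(subsample_membership("N06AB06"), "CYP2C19")
  expect_equal(subsample_membership("N06AB05"), "CYP2D6")
  expect_equal(subsample_membership("N06AX02"), character(0))
})

test_that("reasons are tabulated by enzyme and collapsed metabolizer group", {
  # three CYP2D6 NM patients discontinue paroxetine at the 7 -> 8 transition
  meds <- do.call(rbind, lapply(c("A", "B", "C"), function(p) {
    data.frame(patient_id = p, period = 5:7, atc = "N06AB05")
  }))
  reasons <- data.frame(patient_id = c("A", "B", "C"), period = 7,
                        atc = "N06AB05", reason = "symptom_free")
  ph <- data.frame(patient_id = rep(c("A", "B", "C"), each = 2),
                   gene = rep(c("CYP2D6", "CYP2C19"), 3),
                   status = "NM")
  out <- reasons_table(meds, NULL, reasons, ph)
  expect_equal(out$n[out$enzyme == "CYP2D6" & out$group == "NM" &
                     out$reason == "symptom_free"], 3L)
  expect_equal(sum(out$n), 3L) # paroxetine is CYP2D6-only
  # empty reasons give an all-zero table
  out0 <- reasons_table(meds, NULL, reasons[0, ], ph)
  expect_equal(sum(out0$n), 0L)
})

test_that("a reason without a matching medication change is dropped with a warning", {
  meds <- data.frame(patient_id = "A", period = 1:10, atc = "N06AB05")
  reasons <- data.frame(patient_id = "A", period = 7, atc = "N06AB05",
                        reason = "ineffective")
  ph <- data.frame(patient_id = "A", gene = "CYP2D6", status = "NM")
  expect_warning(out <- reasons_table(meds, NULL, reasons, ph),
                 "without a matching")
  expect_equal(sum(out$n), 0L)
})

test_that("simulated reason proportions recover the configured multinomial", {
  probs <- c(symptom_free = 0.4, ineffective = 0.25, side_effects = 0.35)
  cfg <- cohort_config(n_patients = 500,
                       trajectory_mixture = c(maintained = 0.1, switched = 0.5,
                                              discontinued = 0.4),
                       reason_probs = probs)
  co <- generate_cohort(cfg, seed = 314)
  n <- nrow(co$reasons)
  expect_gt(n, 40)
  obs <- table(factor(co$reasons$reason, levels = names(probs))) / n
  se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(as.numeric(obs) - probs) < 3 * se))
})
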
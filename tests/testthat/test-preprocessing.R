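make_clean_table <- function(n = 4, seed = 17) {
  spec <- model_spec("risk_return")
  ps <- replicate(n, utility_params(alpha = 0.015, beta = 0.3),
                  simplify = FALSE)
  simulate_choices(spec, ps, "PR", seed = seed)
}

test_that("each exclusion criterion is detected on a crafted table", {
  tab <- make_clean_table(5)
  ids <- unique(tab$participant_id)
  # P1: incomplete (drop the last 10 trials)
  drop <- tab$participant_id == ids[1] & tab$trial_index > 122
  tab <- tab[!drop, ]
  # P2: >= 5% non-response
  i2 <- which(tab$participant_id == ids[2])[1:10]
  tab$choice[i2] <- "missing"; tab$outcome[i2] <- NA
  # P3: constant response
  i3 <- tab$participant_id == ids[3]
  tab$choice[i3] <- "reject"; tab$outcome[i3] <- 10
  # P4: > 10% catch errors (flip enough catch responses)
  i4 <- which(tab$participant_id == ids[4] & tab$catch_type != "none")
  tab$choice[i4] <- ifelse(tab$catch_type[i4] == "always_accept",
                           "reject", "accept")
  res <- apply_exclusions(tab)
  rep <- res$report[match(ids, res$report$participant_id), ]
  expect_equal(rep$kept, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_true(rep$incomplete[1])
  expect_true(rep$nonresponse_ge_5pct[2])
  expect_true(rep$constant_response[3])
  expect_true(rep$catch_error_gt_10pct[4])
  expect_equal(rep$reasons[5], "")
  expect_setequal(unique(res$table$participant_id), ids[5])
})

test_that("pooled and per-participant acceptance match a brute-force count", {
  tab <- make_clean_table(4)
  an <- tab[tab$analyzed & tab$choice != "missing", ]
  expect_equal(pooled_acceptance(tab)$q, mean(an$choice == "accept"))
  byb <- pooled_acceptance(tab, by = "block_index")
  for (b in 1:2) {
    sub <- an[an$block_index == b, ]
    expect_equal(byb$q[byb$block_index == b], mean(sub$choice == "accept"))
  }
  pp <- participant_acceptance(tab)
  id <- pp$participant_id[2]
  expect_equal(pp$q[2],
               mean(an$choice[an$participant_id == id] == "accept"))
})

test_that("moving-average acceptance matches a direct window sum", {
  tab <- make_clean_table(3)
  ma <- moving_average_acceptance(tab, k = 2)
  expect_equal(range(ma$trial_index), c(3, 130))
  an <- tab[tab$analyzed & tab$choice != "missing", ]
  for (i in c(3, 70, 130)) {
    win <- an[an$trial_index >= i - 2 & an$trial_index <= i + 2, ]
    row <- ma[ma$trial_index == i, ]
    expect_equal(row$n_choices, nrow(win))
    expect_equal(row$q, mean(win$choice == "accept"))
  }
})

test_that("acceptance curves recover slopes and flag separation", {
  tab <- make_clean_table(6)
  cm <- fit_acceptance_curve(tab, "magnitude")
  cp <- fit_acceptance_curve(tab, "probability")
  # under alpha > 0 acceptance rises with both magnitude and probability
  expect_gt(cm$slope, 0)
  expect_gt(cp$slope, 0)
  expect_false(cm$separation)
  per <- fit_acceptance_curve(tab, "magnitude", per_probability = TRUE)
  expect_equal(sort(per$probability), c(0.4, 0.5, 0.6))
  # a perfectly thresholded responder separates on magnitude
  det <- tab[tab$participant_id == tab$participant_id[1], ]
  det$choice <- ifelse(det$magnitude > 35, "accept", "reject")
  expect_true(fit_acceptance_curve(det, "magnitude")$separation)
  # bootstrap CI brackets the point estimate
  ci <- fit_acceptance_curve(tab, "magnitude", B = 99, seed = 2)
  expect_true(ci$ci_low <= ci$slope && ci$slope <= ci$ci_high)
})
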
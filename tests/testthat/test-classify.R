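make_pm <- function(n_cases_per_class, spots, n_peaks, sep = 0, seed = 1,
                    case_sd = 0.5, noise = 1) {
  # small synthetic feature table: class separation `sep` on every peak
  set.seed(seed)
  rows <- list(); vals <- list()
  for (cl in c("FA", "LGP")) {
    for (ci in seq_len(n_cases_per_class)) {
      case <- sprintf("%s_%02d", cl, ci)
      case_eff <- stats::rnorm(n_peaks, 0, case_sd)
      for (sp in seq_len(spots)) {
        mu <- case_eff + if (cl == "LGP") sep else 0
        vals[[length(vals) + 1L]] <- stats::rnorm(n_peaks, 10 + mu, noise)
        rows[[length(rows) + 1L]] <- data.frame(
          case_id = case, spot_id = sprintf("s%02d", sp),
          compartment = "stromal", class_label = cl,
          stringsAsFactors = FALSE)
      }
    }
  }
  peak_matrix(pmax(do.call(rbind, vals), 0), do.call(rbind, rows),
              seq(900, by = 10, length.out = n_peaks))
}

truth_of <- function(pm) {
  m <- pm$meta[!duplicated(pm$meta$case_id), ]
  stats::setNames(m$class_label, m$case_id)
}

test_that("case-level study/validation split never separates a case", {
  sim <- generate_dataset(tiny_config(n_cases_per_class = c(FA = 5, LGP = 6)))
  ds <- split_dataset(sim$dataset, c(LGP = 4, FA = 3), seed = 2)
  meta <- dataset_meta(ds)
  per_case <- tapply(meta$partition, meta$case_id,
                     function(p) length(unique(p)))
  expect_true(all(per_case == 1))
  by_case <- meta[!duplicated(meta$case_id), ]
  expect_equal(sum(by_case$partition == "validation" &
                     by_case$class_label == "LGP"), 2)
  expect_equal(sum(by_case$partition == "validation" &
                     by_case$class_label == "FA"), 2)
  # deterministic under the seed; boundary request empties validation
  ds2 <- split_dataset(sim$dataset, c(LGP = 4, FA = 3), seed = 2)
  expect_identical(ds$partition, ds2$partition)
  expect_warning(split_dataset(sim$dataset, c(LGP = 6, FA = 5), seed = 1),
                 "empty")
  expect_error(split_dataset(sim$dataset, c(LGP = 9, FA = 3), seed = 1),
               "9 requested")
})

test_that("cost tuning uses case-grouped folds without leakage", {
  pm <- make_pm(6, 4, 5, sep = 3, seed = 3)
  cfg <- svm_config(seed = 4)
  # structural check on fold assignment: a case never straddles folds
  fold <- maldiprofiler:::make_folds(pm$meta, 5, "case", 4)
  expect_true(all(tapply(fold, pm$meta$case_id,
                         function(f) length(unique(f))) == 1))

  fit <- tune_and_train(pm, cfg)
  expect_true(all(fit$cv_accuracy_by_cost$cv_accuracy >= 0.95))

  # singleton grid: the tuned cost is the only candidate
  fit05 <- tune_and_train(pm, svm_config(cost_grid = 0.5, seed = 4))
  expect_equal(fit05$tuned_cost, 0.5)

  # permuted labels: CV accuracy within the binomial null band around 0.5
  accs <- vapply(1:20, function(i) {
    pmn <- pm
    set.seed(100 + i)
    perm <- sample(nrow(pmn$meta))
    pmn$meta$class_label <- pmn$meta$class_label[perm]
    pmn$meta$case_id <- pmn$meta$case_id[perm]
    fitn <- tune_and_train(pmn, svm_config(cost_grid = 1, fold_unit = "spot",
                                           seed = i))
    fitn$cv_accuracy_by_cost$cv_accuracy
  }, numeric(1))
  n_tot <- 20 * nrow(pm$values)
  band <- 1.96 * sqrt(0.25 / n_tot)
  expect_lt(abs(mean(accs) - 0.5), 3 * band)

  expect_error(tune_and_train(subset_peak_matrix(pm, pm$meta$class_label == "FA"),
                              cfg), "2 classes")
})

test_that("spot prediction is deterministic and column-checked", {
  pm <- make_pm(6, 4, 5, sep = 3, seed = 5)
  fit <- tune_and_train(pm, svm_config(seed = 6))
  preds <- predict_spots(fit, pm)
  expect_equal(nrow(preds), nrow(pm$values))
  # training accuracy at least matches CV accuracy
  expect_gte(mean(preds$predicted == pm$meta$class_label),
             max(fit$cv_accuracy_by_cost$cv_accuracy) - 1e-9)
  # a duplicated training row gets the same call as the original
  dup <- subset_peak_matrix(pm, c(1, 1))
  pd <- predict_spots(fit, dup)
  expect_equal(pd$predicted[1], pd$predicted[2])
  # the all-zero row gets a deterministic call
  zero <- pm; zero$values[1, ] <- 0
  z1 <- predict_spots(fit, subset_peak_matrix(zero, 1))
  z2 <- predict_spots(fit, subset_peak_matrix(zero, 1))
  expect_equal(z1$predicted, z2$predicted)
  # mismatched columns are an error naming the offending peaks
  bad <- subset_peak_matrix(pm, 1:4); bad$mz <- bad$mz + 1
  bad$values <- bad$values; expect_error(predict_spots(fit, bad), "columns")
})

test_that("case aggregation computes modal calls, consistency and ties", {
  mk_preds <- function(calls) data.frame(
    case_id = "c1", spot_id = sprintf("s%02d", seq_along(calls)),
    compartment = "stromal", predicted = calls, stringsAsFactors = FALSE)
  all_lgp <- aggregate_cases(mk_preds(rep("LGP", 20)))
  expect_equal(all_lgp$final_call, "LGP")
  expect_equal(all_lgp$consistency, 1.0)

  mixed <- aggregate_cases(mk_preds(c(rep("LGP", 12), rep("FA", 8))),
                           truth = c(c1 = "LGP"))
  expect_equal(mixed$final_call, "LGP")
  expect_equal(mixed$consistency, 0.6)
  expect_true(mixed$correct)

  tie <- aggregate_cases(mk_preds(c(rep("LGP", 10), rep("FA", 10))),
                         truth = c(c1 = "LGP"))
  expect_equal(tie$final_call, "indeterminate")
  expect_false(tie$correct)
})

test_that("evaluation reports accuracy, per-class counts and consistency", {
  calls <- data.frame(
    case_id = sprintf("c%02d", 1:20),
    n_spots = 20,
    final_call = c(rep("LGP", 8), rep("FA", 2), rep("LGP", 8), rep("FA", 2)),
    consistency = c(rep(1, 7), rep(0.75, 13)),
    stringsAsFactors = FALSE)
  truth <- stats::setNames(c(rep("LGP", 10), rep("FA", 10)), calls$case_id)
  ev <- evaluate_cases(calls, truth)
  expect_equal(ev$overall_accuracy, 0.5)
  expect_equal(ev$per_class$correct[ev$per_class$class == "LGP"], 8)
  expect_equal(ev$per_class$correct[ev$per_class$class == "FA"], 2)
  expect_equal(ev$n_fully_consistent, 7)

  # random truth: accuracy equals the brute-force count
  set.seed(42)
  for (i in 1:5) {
    truth_r <- stats::setNames(sample(c("FA", "LGP"), 20, replace = TRUE),
                               calls$case_id)
    ev_r <- evaluate_cases(calls, truth_r)
    expect_equal(ev_r$overall_accuracy,
                 sum(calls$final_call == truth_r) / 20)
  }
})
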
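make_clouds <- function(n = 20, d = 5, offset = 5, seed = 1) {
  set.seed(seed)
  pos <- matrix(rnorm(n * d), n, d) + offset
  neg <- matrix(rnorm(n * d), n, d)
  list(pos = pos, neg = neg)
}

test_that("default hyperparameter registry records the per-scheme settings", {
  p <- default_svm_params("DIPEP", 1)
  expect_equal(c(p$gamma, p$C, p$j), c(265, 6, 1))
  p2 <- default_svm_params("DIPEP", 2)
  expect_equal(c(p2$gamma, p2$C, p2$j), c(210, 1, 2))
  expect_equal(unlist(default_svm_params("NCC", 1)), c(gamma = 20, C = 3, j = 2))
  expect_equal(unlist(default_svm_params("AAC", 2)), c(gamma = 246, C = 1, j = 2))
  expect_error(default_svm_params("BOGUS", 1), class = "plastidclass_usage_error")
  expect_error(svm_params(-1, 1, 1), class = "plastidclass_usage_error")
})

test_that("binary SVM separates well-separated clouds and thresholds monotonically", {
  cl <- make_clouds()
  m <- train_binary(cl$pos, cl$neg, svm_params(0.5, 1), seed = 1)
  x <- rbind(cl$pos, cl$neg)
  truth <- rep(c("pos", "neg"), each = 20)
  expect_equal(predict_binary(m, x), truth)  # separable: 100% training accuracy

  dv <- decision_values(m, x)
  expect_true(all(is.finite(dv)))
  expect_equal(predict_binary(m, x, threshold = 0),
               ifelse(dv >= 0, "pos", "neg"))
  n_calls <- vapply(seq(-2, 2, by = 0.25),
                    function(t) sum(dv >= t), numeric(1))
  expect_true(all(diff(n_calls) <= 0))
  expect_equal(sum(dv >= max(dv) + 1), 0)
})

test_that("swapping class labels negates decision values", {
  cl <- make_clouds(offset = 2, seed = 2)
  m1 <- train_binary(cl$pos, cl$neg, svm_params(0.5, 1, j = 1), seed = 1)
  m2 <- train_binary(cl$neg, cl$pos, svm_params(0.5, 1, j = 1), seed = 1)
  set.seed(3)
  probe <- matrix(rnorm(50), 10, 5) + 1
  expect_equal(decision_values(m1, probe), -decision_values(m2, probe),
               tolerance = 5e-3)
})

test_that("duplicating every training point leaves predictions unchanged", {
  cl <- make_clouds(offset = 1.5, seed = 4)
  m1 <- train_binary(cl$pos, cl$neg, svm_params(0.3, 2), seed = 1)
  m2 <- train_binary(rbind(cl$pos, cl$pos), rbind(cl$neg, cl$neg),
                     svm_params(0.3, 2), seed = 1)
  set.seed(5)
  probe <- matrix(rnorm(100), 20, 5) + 0.75
  expect_equal(predict_binary(m1, probe), predict_binary(m2, probe))
})

test_that("training validates arity and class sizes", {
  cl <- make_clouds()
  expect_error(train_binary(cl$pos[, 1:3], cl$neg, svm_params(1, 1)),
               class = "plastidclass_data_error")
  expect_error(train_binary(cl$pos[1, , drop = FALSE], cl$neg, svm_params(1, 1)),
               class = "plastidclass_data_error")
  m <- train_binary(cl$pos, cl$neg, svm_params(1, 1))
  expect_error(decision_values(m, cl$pos[, 1:2]),
               class = "plastidclass_data_error")
})

test_that("one-vs-one trains k(k-1)/2 machines and votes consistently", {
  set.seed(6)
  mk <- function(center) matrix(rnorm(30 * 4), 30, 4) + rep(center, each = 30)
  cls3 <- list(a = mk(c(0, 0, 0, 0)), b = mk(c(6, 0, 0, 0)),
               c = mk(c(0, 6, 0, 0)))
  m3 <- train_ovo(cls3, svm_params(0.5, 1))
  expect_length(m3$machines, 3L)
  cls4 <- c(cls3, list(d = mk(c(0, 0, 6, 0))))
  m4 <- train_ovo(cls4, svm_params(0.5, 1))
  expect_length(m4$machines, 6L)

  ## deep-inside samples win all their votes; tallies sum to k(k-1)/2
  probe <- rbind(c(6, 0, 0, 0), c(0, 6, 0, 0))
  p <- predict_ovo(m4, probe)
  expect_equal(p$label, c("b", "c"))
  expect_equal(p$votes.b[1], 3L)
  vote_cols <- grep("^votes\\.", names(p))
  expect_equal(unname(rowSums(p[, vote_cols])), rep(6, 2))

  ## two-class OVO degenerates to the corresponding binary machine
  m2 <- train_ovo(cls3[c("a", "b")], svm_params(0.5, 1), seed = 9)
  bin <- m2$machines[[1]]
  set.seed(7)
  q <- matrix(rnorm(40), 10, 4) + 3
  expect_equal(predict_ovo(m2, q)$label, predict_binary(bin, q))

  ## row permutation invariance
  perm <- sample(nrow(q))
  expect_equal(predict_ovo(m4, q[perm, ])$label, predict_ovo(m4, q)$label[perm])

  expect_error(train_ovo(list(a = cls3$a), svm_params(1, 1)),
               class = "plastidclass_data_error")
  expect_error(train_ovo(list(a = cls3$a, b = cls3$b[1, , drop = FALSE]),
                         svm_params(1, 1)),
               class = "plastidclass_data_error")
})

test_that("models round-trip through save/load with checksum verification", {
  cl <- make_clouds(seed = 8)
  m <- train_binary(cl$pos, cl$neg, svm_params(0.5, 1), scheme = "AAC")
  f <- withr::local_tempfile(fileext = ".plm")
  save_model(m, f)
  m2 <- load_model(f, type = "binary")
  probe <- rbind(cl$pos, cl$neg)
  expect_identical(decision_values(m, probe), decision_values(m2, probe))

  expect_error(load_model(f, type = "ovo"), class = "plastidclass_data_error")
  ## tamper with the payload
  obj <- readRDS(f)
  obj$payload[100] <- as.raw(bitwXor(as.integer(obj$payload[100]), 255L))
  saveRDS(obj, f)
  expect_error(load_model(f), "checksum", class = "plastidclass_data_error")
  expect_error(load_model(file.path(tempdir(), "missing.plm")),
               class = "plastidclass_io_error")
})

test_that("two-phase prediction chains the models and tolerates bad records", {
  set.seed(20)
  pr <- default_profiles()
  train1 <- generate_dataset(pr[c("plastid", "nonplastid")], 40, seed = 31)
  x1 <- lapply(split(train1, train1$label), extract, scheme = "AAC")
  p1 <- train_binary(x1$plastid, x1$nonplastid, svm_params(50, 4),
                     scheme = "AAC", positive_label = "plastid",
                     negative_label = "nonplastid")
  train2 <- generate_dataset(pr[c("chloroplast", "chromoplast",
                                  "etioplast", "amyloplast")], 60, seed = 32)
  x2 <- lapply(split(train2, train2$label), extract, scheme = "DIPEP")
  p2 <- train_ovo(x2, default_svm_params("DIPEP", 2), scheme = "DIPEP")

  query <- generate_dataset(pr[c("chloroplast", "nonplastid")], 10, seed = 33)
  res <- two_phase_predict(p1, p2, query)
  expect_equal(res$id, query$id)
  expect_true(all(is.na(res$subtype[res$phase1_call == "nonplastid"])))
  called <- res$phase1_call == "plastid"
  expect_true(all(res$subtype[called] %in% p2$labels))
  ## most true chloroplast queries should be called plastid + chloroplast
  chl <- res[query$label == "chloroplast", ]
  expect_gt(mean(chl$phase1_call == "plastid"), 0.7)
  expect_gt(mean(chl$subtype == "chloroplast", na.rm = TRUE), 0.5)

  ## empty input and per-record failure
  expect_equal(nrow(two_phase_predict(p1, p2, query[0, ])), 0L)
  bad <- query[1:3, ]; bad$sequence[2] <- "A"; bad$length[2] <- 1L
  ## length-1 sequence passes AAC but a DIPEP phase-1 model must flag it
  p1d <- train_binary(extract(train1[train1$label == "plastid", ], "DIPEP"),
                      extract(train1[train1$label == "nonplastid", ], "DIPEP"),
                      svm_params(265, 6), scheme = "DIPEP",
                      positive_label = "plastid", negative_label = "nonplastid")
  res_bad <- two_phase_predict(p1d, p2, bad)
  expect_equal(sum(res_bad$status != "ok"), 1L)
  expect_equal(nrow(res_bad), 3L)
})
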
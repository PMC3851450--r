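## RBF-kernel SVM classifiers: binary phase-I machines, one-vs-one multiclass
## phase-II machines, and the chained two-phase predictor. Fitting is
## delegated to e1071::svm (libsvm); the kernel is K(x,y) = exp(-gamma*|x-y|^2)
## on the raw [0,1]-scale features (scale = FALSE).

#' SVM hyperparameters
#'
#' @param gamma RBF kernel width, `K(x,y) = exp(-gamma * ||x-y||^2)`.
#' @param C soft-margin cost.
#' @param j cost multiplier for errors on positive-class examples
#'   (cost-factor semantics: the penalty for a positive-class training error
#'   is `j * C`).
#' @return an `svm_params` list.
#' @export
svm_params <- function(gamma, C, j = 1) {
  if (gamma <= 0 || C <= 0 || j <= 0)
    stop_usage("gamma, C and j must all be > 0")
  structure(list(gamma = gamma, C = C, j = j), class = "svm_params")
}

## Defaults of record per scheme and phase. These were selected on the
## original curated training corpus; on other data they are starting points,
## not guaranteed optima, and are fully overridable.
DEFAULT_SVM_PARAMS <- list(
  phase1 = list(
    AAC      = list(gamma = 370, C = 3, j = 1),
    PSEAAC   = list(gamma = 385, C = 2, j = 2),
    DIPEP    = list(gamma = 265, C = 6, j = 1),
    NCC      = list(gamma = 20,  C = 3, j = 2),
    PHYSCHEM = list(gamma = 135, C = 2, j = 1)),
  phase2 = list(
    AAC      = list(gamma = 246, C = 1, j = 2),
    PSEAAC   = list(gamma = 225, C = 1, j = 2),
    DIPEP    = list(gamma = 210, C = 1, j = 2),
    NCC      = list(gamma = 5,   C = 2, j = 3),
    PHYSCHEM = list(gamma = 37,  C = 9, j = 1)))

#' Default RBF hyperparameters per feature scheme and phase
#'
#' Returns the recorded (gamma, C, j) triple for a scheme in phase I
#' (plastid vs non-plastid) or phase II (plastid-type OVO), e.g. DIPEP
#' phase I is gamma = 265, C = 6, j = 1.
#'
#' @param scheme feature scheme name.
#' @param phase 1 or 2.
#' @return an [svm_params] object.
#' @export
default_svm_params <- function(scheme, phase = 1) {
  ph <- paste0("phase", phase)
  if (!ph %in% names(DEFAULT_SVM_PARAMS)) stop_usage("phase must be 1 or 2")
  p <- DEFAULT_SVM_PARAMS[[ph]][[scheme]]
  if (is.null(p)) stop_usage(sprintf("no default parameters for scheme '%s'", scheme))
  svm_params(p$gamma, p$C, p$j)
}

MODEL_FORMAT_VERSION <- "plastidclass-model-1"

#' Train a binary RBF-SVM
#'
#' Fits a soft-margin RBF SVM separating a positive from a negative feature
#' matrix. The cost factor `j` multiplies the penalty on positive-class
#' errors (via per-class weights). Training is deterministic given the
#' inputs, parameters and seed.
#'
#' @param pos,neg numeric feature matrices (rows = examples) of equal arity.
#' @param params an [svm_params] object.
#' @param seed integer seed recorded with the model.
#' @param scheme optional feature scheme name (taken from the matrix
#'   attribute when present).
#' @param feature_params optional list of scheme parameters, stored so
#'   prediction from raw sequences recomputes identical features.
#' @param positive_label,negative_label class labels (defaults "pos"/"neg").
#' @return a `binary_model` object.
#' @export
train_binary <- function(pos, neg, params, seed = 1L,
                         scheme = attr(pos, "scheme"),
                         feature_params = list(),
                         positive_label = "pos", negative_label = "neg") {
  if (!nrow(pos) || !nrow(neg)) stop_data("both classes must be non-empty")
  if (nrow(pos) < 2L || nrow(neg) < 2L)
    stop_data("each class needs >= 2 training examples")
  if (ncol(pos) != ncol(neg))
    stop_data(sprintf("feature arity mismatch: %d vs %d", ncol(pos), ncol(neg)))
  set.seed(seed)
  x <- rbind(pos, neg)
  y <- factor(rep(c(positive_label, negative_label), c(nrow(pos), nrow(neg))),
              levels = c(positive_label, negative_label))
  cw <- setNames(c(params$j, 1), c(positive_label, negative_label))
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    gamma = params$gamma, cost = params$C,
                    class.weights = cw, scale = FALSE)
  ## fix the decision-value sign so positive class scores high
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")[, 1]
  sign_flip <- if (mean(dv[y == positive_label]) < mean(dv[y == negative_label])) -1 else 1
  structure(list(fit = fit, sign = sign_flip,
                 params = params, scheme = scheme,
                 feature_params = feature_params,
                 positive_label = positive_label,
                 negative_label = negative_label,
                 n_pos = nrow(pos), n_neg = nrow(neg), seed = seed,
                 arity = ncol(pos)),
            class = "binary_model")
}

#' Decision values of a binary model
#'
#' Signed margins; positive-class examples score high. Thresholding at `t`
#' reproduces `predict_binary(..., threshold = t)`.
#'
#' @param model a `binary_model`.
#' @param x feature matrix with the model's arity.
#' @return numeric vector, one value per row of `x`.
#' @export
decision_values <- function(model, x) {
  if (!inherits(model, "binary_model")) stop_usage("not a binary model")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$arity)
    stop_data(sprintf("feature arity mismatch: model expects %d, got %d",
                      model$arity, ncol(x)))
  if (nrow(x) == 0L) return(numeric(0))
  dv <- attr(predict(model$fit, x, decision.values = TRUE),
             "decision.values")[, 1]
  unname(model$sign * dv)
}

#' Predict class calls from a binary model
#'
#' @inheritParams decision_values
#' @param threshold decision threshold on the margin (default 0.0, the SVM's
#'   native decision rule).
#' @return character vector of labels.
#' @export
predict_binary <- function(model, x, threshold = 0) {
  ifelse(decision_values(model, x) >= threshold,
         model$positive_label, model$negative_label)
}

#' Train a one-vs-one multiclass SVM
#'
#' Fits one binary RBF machine per unordered class pair (k classes give
#' k(k-1)/2 machines); prediction is by majority vote.
#'
#' @param class_matrices named list mapping class label to its feature
#'   matrix; all matrices must share arity.
#' @param params a single [svm_params] shared by every pair, or a named list
#'   `"A|B"` (labels in the list's class order) of per-pair parameters.
#' @param seed integer seed.
#' @param scheme,feature_params as in [train_binary].
#' @return an `ovo_model` object.
#' @export
train_ovo <- function(class_matrices, params, seed = 1L,
                      scheme = attr(class_matrices[[1]], "scheme"),
                      feature_params = list()) {
  labels <- names(class_matrices)
  if (length(labels) < 2L) stop_data("OVO needs >= 2 classes")
  ns <- vapply(class_matrices, nrow, integer(1))
  if (any(ns < 2L))
    stop_data(sprintf("class '%s' has < 2 examples", labels[which(ns < 2L)[1]]))
  arities <- vapply(class_matrices, ncol, integer(1))
  if (length(unique(arities)) != 1L) stop_data("feature arity mismatch across classes")
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  machines <- lapply(seq_along(pairs), function(k) {
    pr <- pairs[[k]]
    p <- if (inherits(params, "svm_params")) params else {
      key <- paste(pr, collapse = "|")
      if (is.null(params[[key]])) stop_usage(sprintf("no parameters for pair '%s'", key))
      params[[key]]
    }
    train_binary(class_matrices[[pr[1]]], class_matrices[[pr[2]]], p,
                 seed = seed + k, scheme = scheme,
                 feature_params = feature_params,
                 positive_label = pr[1], negative_label = pr[2])
  })
  names(machines) <- vapply(pairs, paste, character(1), collapse = "|")
  structure(list(labels = labels, machines = machines, params = params,
                 scheme = scheme, feature_params = feature_params,
                 seed = seed, arity = unique(arities)),
            class = "ovo_model")
}

#' Predict with a one-vs-one multiclass model
#'
#' Each pairwise machine casts one vote per sample; the label with most
#' votes wins. Ties are broken by the largest summed absolute margin among
#' the tied classes, then by class order.
#'
#' @param model an `ovo_model`.
#' @param x feature matrix.
#' @return data frame with `label`, one `votes.<class>` column per class,
#'   and one `margin.<class>` column (summed absolute winning margins).
#' @export
predict_ovo <- function(model, x) {
  if (!inherits(model, "ovo_model")) stop_usage("not an OVO model")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$arity)
    stop_data(sprintf("feature arity mismatch: model expects %d, got %d",
                      model$arity, ncol(x)))
  k <- length(model$labels)
  n <- nrow(x)
  votes <- matrix(0L, n, k, dimnames = list(NULL, model$labels))
  margin <- matrix(0, n, k, dimnames = list(NULL, model$labels))
  for (m in model$machines) {
    dv <- decision_values(m, x)
    win <- ifelse(dv >= 0, m$positive_label, m$negative_label)
    for (cl in model$labels) {
      hit <- win == cl
      votes[hit, cl] <- votes[hit, cl] + 1L
      margin[hit, cl] <- margin[hit, cl] + abs(dv[hit])
    }
  }
  label <- character(n)
  for (i in seq_len(n)) {
    best <- which(votes[i, ] == max(votes[i, ]))
    if (length(best) > 1L) best <- best[which.max(margin[i, best])]
    label[i] <- model$labels[best[1]]
  }
  out <- data.frame(label = label, stringsAsFactors = FALSE)
  colnames(votes) <- paste0("votes.", model$labels)
  colnames(margin) <- paste0("margin.", model$labels)
  cbind(out, as.data.frame(votes), as.data.frame(margin))
}

#' Chained two-phase prediction from sequences
#'
#' Runs the full pipeline on raw protein records: phase I scores each record
#' with the binary plastid vs non-plastid model at the given threshold;
#' records called plastid are passed to the phase-II multiclass model for
#' subtype assignment. The two phases may use different feature schemes;
#' features are computed per phase from each model's stored scheme. Records
#' failing a scheme precondition get a per-record failure status; the run
#' continues.
#'
#' @param phase1 a `binary_model` (positive class = plastid).
#' @param phase2 an `ovo_model` over the plastid types.
#' @param records a `protein_records` table.
#' @param threshold phase-I decision threshold (default 0.0).
#' @return data frame, one row per input record in input order: `id`,
#'   `status` ("ok" or the failure reason), `phase1_score`, `phase1_call`,
#'   `subtype` (NA for non-plastid calls), plus phase-II vote columns.
#' @export
two_phase_predict <- function(phase1, phase2, records, threshold = 0) {
  n <- nrow(records)
  out <- data.frame(id = records$id, status = rep("ok", n),
                    phase1_score = rep(NA_real_, n),
                    phase1_call = rep(NA_character_, n),
                    subtype = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  x1 <- extract(records, phase1$scheme, phase1$feature_params)
  exc <- attr(x1, "excluded")
  if (nrow(exc)) out$status[match(exc$id, out$id)] <- exc$reason
  ok1 <- rownames(x1)
  idx1 <- match(ok1, out$id)
  sc <- decision_values(phase1, x1)
  out$phase1_score[idx1] <- sc
  out$phase1_call[idx1] <- ifelse(sc >= threshold, phase1$positive_label,
                                  phase1$negative_label)
  plastid_ids <- ok1[sc >= threshold]
  if (length(plastid_ids)) {
    rec2 <- records[match(plastid_ids, records$id), , drop = FALSE]
    x2 <- extract(rec2, phase2$scheme, phase2$feature_params)
    exc2 <- attr(x2, "excluded")
    if (nrow(exc2)) out$status[match(exc2$id, out$id)] <- exc2$reason
    if (nrow(x2)) {
      p2 <- predict_ovo(phase2, x2)
      out$subtype[match(rownames(x2), out$id)] <- p2$label
    }
  }
  out
}

#' Save / load a trained model
#'
#' Models are stored as a single-file archive embedding the feature scheme,
#' kernel parameters, residue ordering, a format version and a checksum.
#' Loading verifies the version and checksum; `load_model(save_model(m))`
#' yields identical decision values.
#'
#' @param model a `binary_model` or `ovo_model`.
#' @param path file path.
#' @return `load_model`: the model; `save_model`: invisibly, `path`.
#' @export
save_model <- function(model, path) {
  type <- if (inherits(model, "binary_model")) "binary"
          else if (inherits(model, "ovo_model")) "ovo"
          else stop_usage("not a saveable model")
  payload <- serialize(model, NULL, xdr = TRUE)
  obj <- list(format = MODEL_FORMAT_VERSION, type = type,
              residue_order = AA_ALPHABET20,
              checksum = raw_checksum(payload), payload = payload)
  tryCatch(saveRDS(obj, path),
           error = function(e) stop_io(sprintf("cannot write model to '%s'", path)))
  invisible(path)
}

#' @rdname save_model
#' @param type expected model type (`"binary"`, `"ovo"`, or `"any"`); a
#'   mismatch is a typed error so phase-I and phase-II files cannot be
#'   confused.
#' @export
load_model <- function(path, type = "any") {
  if (!file.exists(path)) stop_io(sprintf("model file '%s' not found", path))
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop_io(sprintf("cannot read model file '%s'", path)))
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT_VERSION))
    stop_data(sprintf("'%s' is not a %s file", path, MODEL_FORMAT_VERSION))
  if (!identical(raw_checksum(obj$payload), obj$checksum))
    stop_data(sprintf("model file '%s' is corrupted (checksum mismatch)", path))
  if (type != "any" && !identical(obj$type, type))
    stop_data(sprintf("expected a %s model but '%s' contains a %s model",
                      type, path, obj$type))
  unserialize(obj$payload)
}
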
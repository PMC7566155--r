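#' Fit a naive Bayes place-of-death classifier
#'
#' Fits a categorical naive Bayes model: class priors and per-feature,
#' per-class conditional tables with Laplace-style smoothing weight
#' `alpha`.  Priors are `(count_c + alpha) / (n + alpha * K)` and
#' conditionals `(count_fc + alpha) / (count_c + alpha * K_f)`, with `K`
#' the number of classes and `K_f` the number of levels of feature `f`.
#' Records missing a feature are simply excluded from that feature's
#' counts (and from its per-class denominators), so partially assessed
#' charts still contribute everything they contain.
#'
#' @param cohort data frame of categorical columns (use
#'   [discretize_cohort()] first for day-count columns).
#' @param class_variable name of the class column; must have no missing
#'   values.
#' @param features character vector of feature column names.
#' @param alpha smoothing weight (default 1, Laplace).  `alpha = 0`
#'   yields raw frequencies and permits zero probabilities.
#' @param missing_values values treated as missing in feature columns
#'   (in addition to `NA`).
#' @param feature_levels optional named list fixing a feature's level
#'   vocabulary (levels absent from the data then get their smoothed
#'   prior mass); by default levels are taken from the data.  Needed
#'   when a rare level may be absent from a training subset, e.g.
#'   during leave-one-out refits.
#' @return Object of class `nb_model` with `prior`, `cond` (one
#'   levels-by-classes matrix per feature), `feature_levels`,
#'   `class_levels`, `alpha` and `dropped_features`.
#' @examples
#' d <- data.frame(x = c("x1", "x1", "x2", "x2"),
#'                 y = c("h", "h", "h", "o"))
#' m <- fit_naive_bayes(d, "y", "x", alpha = 1)
#' predict(m, data.frame(x = "x2"), type = "prob")  # P(h | x2) = 0.545
#' @seealso [predict.nb_model()], [evaluate_classifier()]
#' @export
fit_naive_bayes <- function(cohort, class_variable, features, alpha = 1,
                            missing_values = c("not_assessed",
                                               "not_available"),
                            feature_levels = NULL) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop_credal("credalpod_fit_error", "cohort is empty")
  if (!class_variable %in% names(cohort))
    stop_credal("credalpod_fit_error", "class column '%s' not found",
                class_variable)
  if (any(!features %in% names(cohort)))
    stop_credal("credalpod_fit_error", "feature column '%s' not found",
                setdiff(features, names(cohort))[1L])
  y <- as.character(cohort[[class_variable]])
  if (anyNA(y) || any(y %in% missing_values))
    stop_credal("credalpod_fit_error", "class column has missing values")
  class_levels <- levels(factor(cohort[[class_variable]]))
  if (is.factor(cohort[[class_variable]]))
    class_levels <- levels(cohort[[class_variable]])
  if (length(class_levels) < 2L)
    stop_credal("credalpod_fit_error",
                "class column has a single class; nothing to learn")
  K <- length(class_levels)
  n <- length(y)
  yf <- factor(y, levels = class_levels)
  prior <- (as.numeric(table(yf)) + alpha) / (n + alpha * K)
  names(prior) <- class_levels

  fixed_levels <- feature_levels
  cond <- list(); feature_levels <- list(); dropped <- character(0)
  for (f in features) {
    v <- as.character(cohort[[f]])
    v[v %in% missing_values] <- NA_character_
    lv <- if (!is.null(fixed_levels[[f]])) fixed_levels[[f]]
    else if (is.factor(cohort[[f]]))
      setdiff(levels(cohort[[f]]), missing_values)
    else sort(unique(v[!is.na(v)]))
    if (length(lv) == 0L) {
      warning(sprintf("feature '%s' is entirely missing; dropped", f),
              call. = FALSE)
      dropped <- c(dropped, f)
      next
    }
    present <- !is.na(v)
    tab <- table(factor(v[present], levels = lv),
                 factor(y[present], levels = class_levels))
    denom <- matrix(colSums(tab) + alpha * length(lv),
                    nrow = length(lv), ncol = K, byrow = TRUE)
    cm <- (unclass(tab) + alpha) / denom
    cm[is.nan(cm)] <- 0  # alpha = 0 and class absent among present rows
    dimnames(cm) <- list(lv, class_levels)
    cond[[f]] <- cm
    feature_levels[[f]] <- lv
  }
  structure(list(class_variable = class_variable,
                 class_levels = class_levels, prior = prior, cond = cond,
                 feature_levels = feature_levels, alpha = alpha,
                 missing_values = missing_values, n = n,
                 dropped_features = dropped),
            class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("Naive Bayes classifier: %s (%s), %d features, alpha = %g, n = %d\n",
              x$class_variable, paste(x$class_levels, collapse = "/"),
              length(x$cond), x$alpha, x$n))
  invisible(x)
}

#' @export
summary.nb_model <- function(object, ...) {
  print(object)
  cat("priors:\n")
  print(round(object$prior, 4))
  invisible(object)
}

#' Predict place of death for new records
#'
#' Posterior class probabilities proportional to
#' `prior * prod(P(feature | class))` over the features *present* in the
#' record; missing features are skipped, so a fully missing record falls
#' back to the prior.  The predicted class is the argmax, ties broken by
#' canonical class order.
#'
#' @param object an [fit_naive_bayes()] model.
#' @param newdata data frame of records (missing features as `NA` or a
#'   configured missing marker).
#' @param type `"class"` (factor of predictions) or `"prob"`
#'   (matrix of normalized posteriors).
#' @param ... unused.
#' @return Factor or matrix according to `type`.
#' @export
predict.nb_model <- function(object, newdata, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  if (!is.data.frame(newdata)) newdata <- as.data.frame(newdata)
  K <- length(object$class_levels)
  probs <- matrix(NA_real_, nrow(newdata), K,
                  dimnames = list(NULL, object$class_levels))
  for (r in seq_len(nrow(newdata))) {
    ## work in probability space: tiny feature counts, no underflow risk;
    ## alpha = 0 zeros must propagate exactly
    p <- object$prior
    for (f in names(object$cond)) {
      if (!f %in% names(newdata)) next
      val <- as.character(newdata[[f]][r])
      if (is.na(val) || val %in% object$missing_values) next
      if (!val %in% object$feature_levels[[f]])
        stop_credal("credalpod_prediction_error",
                    "unknown value '%s' for feature '%s'", val, f)
      p <- p * object$cond[[f]][val, ]
    }
    s <- sum(p)
    probs[r, ] <- if (s > 0) p / s else rep(1 / K, K)
  }
  if (type == "prob") return(probs)
  factor(object$class_levels[apply(probs, 1L, which.max)],
         levels = object$class_levels)
}

#' Evaluate a classifier against labels and a recorded baseline
#'
#' Reports in-sample accuracy, leave-one-out cross-validated accuracy
#' (each record predicted by a model refitted without it), the per-class
#' confusion matrix, and — when a baseline prediction column is supplied,
#' such as the care team's recorded prediction — the baseline's accuracy
#' side by side.
#'
#' @param model an [fit_naive_bayes()] model.
#' @param cohort labelled data frame (must contain the model's class
#'   column and features).
#' @param baseline optional name of a column holding baseline
#'   predictions on the class variable's state space.
#' @param loocv compute leave-one-out accuracy (default TRUE).
#' @return Object of class `nb_evaluation`.
#' @export
evaluate_classifier <- function(model, cohort, baseline = NULL,
                                loocv = TRUE) {
  cv <- model$class_variable
  if (!cv %in% names(cohort))
    stop_credal("credalpod_evaluation_error", "class column '%s' missing", cv)
  y <- as.character(cohort[[cv]])
  if (anyNA(y) || any(y %in% model$missing_values))
    stop_credal("credalpod_evaluation_error", "missing labels in '%s'", cv)
  pred <- as.character(predict(model, cohort, type = "class"))
  acc <- mean(pred == y)
  confusion <- table(predicted = factor(pred, model$class_levels),
                     actual = factor(y, model$class_levels))
  baseline_acc <- NULL
  if (!is.null(baseline)) {
    if (!baseline %in% names(cohort))
      stop_credal("credalpod_evaluation_error",
                  "baseline column '%s' missing", baseline)
    b <- as.character(cohort[[baseline]])
    bad <- setdiff(unique(b[!is.na(b)]), model$class_levels)
    if (length(bad))
      stop_credal("credalpod_evaluation_error",
                  "baseline value '%s' outside the class state space", bad[1L])
    baseline_acc <- mean(b == y, na.rm = FALSE)
  }
  loocv_acc <- NULL
  if (loocv) {
    feats <- names(model$cond)
    hits <- vapply(seq_len(nrow(cohort)), function(i) {
      m <- fit_naive_bayes(cohort[-i, , drop = FALSE], cv, feats,
                           alpha = model$alpha,
                           missing_values = model$missing_values,
                           feature_levels = model$feature_levels)
      as.character(predict(m, cohort[i, , drop = FALSE])) == y[i]
    }, TRUE)
    loocv_acc <- mean(hits)
  }
  structure(list(accuracy = acc, baseline_accuracy = baseline_acc,
                 loocv_accuracy = loocv_acc, confusion = confusion,
                 n = nrow(cohort)),
            class = "nb_evaluation")
}

#' @export
print.nb_evaluation <- function(x, ...) {
  cat(sprintf("model accuracy (in-sample): %.3f  (n = %d)\n", x$accuracy, x$n))
  if (!is.null(x$loocv_accuracy))
    cat(sprintf("model accuracy (LOOCV):     %.3f\n", x$loocv_accuracy))
  if (!is.null(x$baseline_accuracy))
    cat(sprintf("baseline accuracy:          %.3f\n", x$baseline_accuracy))
  cat("confusion (predicted x actual):\n")
  print(x$confusion)
  invisible(x)
}

#' Default discretization of day-count columns
#'
#' Chart-review day counts enter the classifier as categories.  Hospital
#' days in the 60 days before assessment are binned 0 / 1-14 / >14
#' (`none`, `short`, `long`, matching the network's `hospital_days`
#' variable); the assessment-to-death interval is split at its sample
#' tertiles.
#'
#' @return Named list of binning rules consumed by [discretize_cohort()].
#' @export
default_discretization <- function() {
  list(
    days_in_hospital_60 = list(new_name = "hospital_days",
                               breaks = c(-Inf, 0, 14, Inf),
                               labels = c("none", "short", "long")),
    assessment_to_death_days = list(new_name = "assessment_interval",
                                    breaks = "tertiles",
                                    labels = c("short", "medium", "long"))
  )
}

#' Apply a discretization config to a cohort
#'
#' @param cohort data frame.
#' @param config list of rules as in [default_discretization()]; rules
#'   for absent columns are skipped.
#' @return The cohort with the binned columns appended.
#' @export
discretize_cohort <- function(cohort, config = default_discretization()) {
  for (col in names(config)) {
    if (!col %in% names(cohort)) next
    rule <- config[[col]]
    x <- cohort[[col]]
    breaks <- rule$breaks
    if (identical(breaks, "tertiles"))
      breaks <- unique(c(-Inf, stats::quantile(x, c(1, 2) / 3, na.rm = TRUE),
                         Inf))
    labs <- rule$labels[seq_len(length(breaks) - 1L)]
    cohort[[rule$new_name]] <- as.character(cut(x, breaks = breaks,
                                                labels = labs,
                                                include.lowest = TRUE))
  }
  cohort
}
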
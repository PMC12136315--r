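# Deviation prediction and uniform compensation: an LSTM stack forecasts
# the cumulative infusion deviation one step ahead; the forecast for the
# final planned infusion is spread evenly over all infusions as a
# feed-forward add-on to each commanded dose.

#' Deviation series from an infusion log
#'
#' The substrate of compensation: per-infusion deviation in dose units
#' (`commanded - delivered`, positive = under-delivery) and its running
#' (cumulative) sum.
#'
#' @param log An [infusion_log()] of repeated fixed-dose infusions, or a
#'   numeric vector of per-infusion deviations in U.
#' @param commanded_dose_U Commanded dose (needed only when `log` is a bare
#'   deviation vector).
#' @return List of class `deviation_series` with `per_infusion_deviation_U`,
#'   `cumulative_deviation_U` (exact prefix sum), `commanded_dose_U`, `n`.
#' @export
deviation_series <- function(log, commanded_dose_U = NULL) {
  if (inherits(log, "data.frame")) {
    dev <- log$commanded_dose_U - log$delivered_dose_U
    commanded_dose_U <- log$commanded_dose_U[1]
  } else {
    dev <- as.numeric(log)
    if (is.null(commanded_dose_U)) {
      stop("`commanded_dose_U` is required for a bare deviation vector",
           call. = FALSE)
    }
  }
  structure(
    list(per_infusion_deviation_U = dev,
         cumulative_deviation_U = cumsum(dev),
         commanded_dose_U = commanded_dose_U,
         n = length(dev)),
    class = "deviation_series"
  )
}

#' Mean absolute percentage error
#'
#' `mean(|a - p| / |a|) * 100` over entries with non-zero actuals; zero
#' actuals are excluded (the ratio is undefined there).
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return MAPE in percent.
#' @export
mape <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("`actual` and `predicted` must have equal length", call. = FALSE)
  }
  keep <- actual != 0
  if (!any(keep)) {
    stop("all actual values are zero; MAPE is undefined", call. = FALSE)
  }
  mean(abs(actual[keep] - predicted[keep]) / abs(actual[keep])) * 100
}

#' Root mean square error
#'
#' @param actual,predicted Equal-length, non-empty numeric vectors.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) == 0) {
    stop("`actual` and `predicted` must be equal-length, non-empty",
         call. = FALSE)
  }
  sqrt(mean((actual - predicted)^2))
}

#' Model specification for the deviation predictor
#'
#' Defaults follow the configuration found optimal for a 120-infusion
#' series: an LSTM-dense-LSTM (`"LDL"`) stack, 32 hidden units, 300 epochs,
#' batch size 256 (i.e. full-batch at this series length), an 85/15
#' chronological split and a 10-sample sliding window with one-step-ahead
#' targets.
#'
#' @param layer_pattern String over `{L, D}` of length 3-4; `L` is a
#'   recurrent (LSTM) layer, `D` a tanh dense layer. A linear head mapping
#'   the last timestep to a single value is always appended.
#' @param hidden_units Units per layer.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size (capped at the training-sample count).
#' @param train_fraction Chronological train share in (0, 1).
#' @param window_length Sliding-window length (input samples per target).
#' @param learning_rate,momentum SGD-with-momentum optimiser settings.
#' @param clip Global gradient-norm clip.
#' @param accuracy_band Relative band for the accuracy curves: a prediction
#'   counts as correct when within this fraction of the target (default 5%).
#' @param seed Seed for weight initialisation and minibatch order.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(layer_pattern = "LDL", hidden_units = 32,
                       epochs = 300, batch_size = 256,
                       train_fraction = 0.85, window_length = 10,
                       learning_rate = 0.05, momentum = 0.9,
                       clip = 1.0, accuracy_band = 0.05, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (window_length < 1 || epochs < 0 || batch_size < 1 || hidden_units < 1) {
    stop("invalid model dimensions", call. = FALSE)
  }
  structure(
    list(layer_pattern = layer_pattern, hidden_units = as.integer(hidden_units),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         train_fraction = train_fraction,
         window_length = as.integer(window_length),
         learning_rate = learning_rate, momentum = momentum, clip = clip,
         accuracy_band = accuracy_band, seed = as.integer(seed)),
    class = "model_spec"
  )
}

#' Chronological train/test split
#'
#' Contiguous, time-ordered partition of the cumulative-deviation series at
#' `floor(n * train_fraction)`; no shuffling (a temporal series shuffled
#' across the boundary would leak drift into the test set).
#'
#' @param series A [deviation_series()].
#' @param train_fraction Train share in (0, 1).
#' @param window_length If supplied, the split errors when the test part is
#'   too short to hold even one sliding window plus target.
#' @return List with `train` and `test` numeric vectors (cumulative
#'   deviation) and `n_train`.
#' @export
chronological_split <- function(series, train_fraction,
                                window_length = NULL) {
  stopifnot(inherits(series, "deviation_series"))
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- series$n
  n_train <- floor(n * train_fraction)
  cum <- series$cumulative_deviation_U
  train <- cum[seq_len(n_train)]
  test <- cum[seq.int(n_train + 1L, length.out = n - n_train)]
  if (!is.null(window_length) && length(test) < window_length + 1L) {
    stop("test split (", length(test), " entries) is too short for window ",
         "length ", window_length, call. = FALSE)
  }
  list(train = train, test = test, n_train = n_train)
}

# sliding windows over a vector: rows = samples, cols = window; target is
# the next entry
make_windows <- function(x, w) {
  n_s <- length(x) - w
  if (n_s < 1L) return(list(X = matrix(0, 0, w), y = numeric(0)))
  X <- t(vapply(seq_len(n_s), function(i) x[i:(i + w - 1L)], numeric(w)))
  list(X = X, y = x[(w + 1L):length(x)])
}

#' Fit the deviation predictor
#'
#' Trains the recurrent stack on sliding windows of the cumulative-deviation
#' series (standardised on the training split) by minibatch gradient descent
#' with momentum and gradient-norm clipping, one-step-ahead mean-squared
#' error. The linear head predicts the increment over the window's final
#' value (a residual connection), so a trending cumulative series does not
#' force the saturating recurrent stack to extrapolate its absolute level.
#' Deterministic given `spec$seed`.
#'
#' @param series A [deviation_series()].
#' @param spec A [model_spec()].
#' @return List of class `deviation_fit`: the trained `stack`, scaling
#'   constants, `spec`, test-set `mape` (percent) and `rmse` (U), per-epoch
#'   `train_curve`/`test_curve` (MSE loss, original units squared) and
#'   `train_accuracy`/`test_accuracy` (fraction of predictions within the
#'   spec's relative band).
#' @export
fit_deviation_model <- function(series, spec = model_spec()) {
  stopifnot(inherits(series, "deviation_series"), inherits(spec, "model_spec"))
  sp <- chronological_split(series, spec$train_fraction, spec$window_length)
  if (length(sp$train) < spec$window_length + 1L) {
    stop("training split is too short for the window length", call. = FALSE)
  }
  mu <- mean(sp$train)
  sdv <- stats::sd(sp$train)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  scale_fn <- function(x) (x - mu) / sdv

  tr <- make_windows(scale_fn(sp$train), spec$window_length)
  te <- make_windows(scale_fn(sp$test), spec$window_length)
  w <- spec$window_length
  # residual targets: increment over the window's last value
  tr$yr <- tr$y - tr$X[, w]
  te$yr <- te$y - if (nrow(te$X)) te$X[, w] else numeric(0)

  with_seed(spec$seed, {
    stack <- build_stack(spec$layer_pattern, spec$hidden_units)
    vel <- zero_velocity(stack)
    n_tr <- nrow(tr$X)
    bs <- min(spec$batch_size, n_tr)
    n_batch <- ceiling(n_tr / bs)
    train_curve <- numeric(spec$epochs)
    test_curve <- numeric(spec$epochs)
    train_acc <- numeric(spec$epochs)
    test_acc <- numeric(spec$epochs)

    eval_part <- function(X, y) {
      if (nrow(X) == 0) return(list(loss = NA_real_, acc = NA_real_,
                                    pred = numeric(0)))
      pred <- stack_predict(stack, X) + X[, w]
      y0 <- y * sdv + mu
      p0 <- pred * sdv + mu
      ok <- abs(p0 - y0) <= spec$accuracy_band * abs(y0)
      list(loss = mean((p0 - y0)^2), acc = mean(ok), pred = p0)
    }

    for (ep in seq_len(spec$epochs)) {
      for (b in seq_len(n_batch)) {
        idx <- seq.int((b - 1L) * bs + 1L, min(b * bs, n_tr))
        xs <- windows_to_xs(tr$X[idx, , drop = FALSE])
        fw <- stack_forward(stack, xs)
        resid <- fw$pred - tr$yr[idx]
        if (!all(is.finite(resid))) {
          stop(structure(
            class = c("pumptwin_training_diverged", "error", "condition"),
            list(message = "deviation-model training diverged", call = NULL)))
        }
        grads <- stack_backward(stack, fw, 2 * resid / length(idx))
        grads <- clip_grads(grads, spec$clip)
        upd <- sgd_update(stack, grads, vel, spec$learning_rate,
                          spec$momentum)
        stack <- upd$stack
        vel <- upd$vel
      }
      etr <- eval_part(tr$X, tr$y)
      ete <- eval_part(te$X, te$y)
      train_curve[ep] <- etr$loss
      test_curve[ep] <- ete$loss
      train_acc[ep] <- etr$acc
      test_acc[ep] <- ete$acc
    }

    ete <- eval_part(te$X, te$y)
    y_test <- te$y * sdv + mu
    structure(
      list(stack = stack, mu = mu, sd = sdv, spec = spec,
           mape = if (length(y_test)) mape(y_test, ete$pred) else NA_real_,
           rmse = if (length(y_test)) rmse(y_test, ete$pred) else NA_real_,
           train_curve = train_curve, test_curve = test_curve,
           train_accuracy = train_acc, test_accuracy = test_acc,
           n_train = sp$n_train, n = series$n),
      class = "deviation_fit"
    )
  })
}

#' @export
print.deviation_fit <- function(x, ...) {
  cat(sprintf(
    "Deviation model %s (%d units): test MAPE %.2f%%, RMSE %.4f U (n=%d, %d/%d split)\n",
    x$spec$layer_pattern, x$spec$hidden_units, x$mape, x$rmse, x$n,
    x$n_train, x$n - x$n_train))
  invisible(x)
}

#' One-step-ahead predictions over a series
#'
#' @param fit A `deviation_fit`.
#' @param series A [deviation_series()].
#' @return Data frame with `index` (target position in the series) and
#'   `predicted_cumulative_U`, one row per sliding window.
#' @export
predict_deviation <- function(fit, series) {
  stopifnot(inherits(fit, "deviation_fit"), inherits(series, "deviation_series"))
  w <- fit$spec$window_length
  x <- (series$cumulative_deviation_U - fit$mu) / fit$sd
  wd <- make_windows(x, w)
  if (nrow(wd$X) == 0) stop("series shorter than the model window",
                            call. = FALSE)
  pred <- stack_predict(fit$stack, wd$X) + wd$X[, w]
  data.frame(index = (w + 1L):series$n,
             predicted_cumulative_U = pred * fit$sd + fit$mu)
}

#' Predicted total (final cumulative) deviation
#'
#' The model's one-step-ahead forecast for the final infusion of the series,
#' i.e. the predicted cumulative deviation after the last planned event —
#' the quantity that gets spread across infusions by [make_plan()].
#'
#' @inheritParams predict_deviation
#' @return Predicted cumulative deviation at the final index, U.
#' @export
predicted_total_deviation <- function(fit, series) {
  pr <- predict_deviation(fit, series)
  pr$predicted_cumulative_U[nrow(pr)]
}

#' Grid search over training hyperparameters
#'
#' Fits every combination of the supplied epoch/batch/hidden-unit lattice
#' (default: epochs {100, 300, 500, 700} x batch {128, 256} x hidden
#' {32, 64} — 16 cells) and ranks by test MAPE ascending, ties broken by
#' RMSE then by fewer epochs. Cells whose training diverges are ranked last
#' and flagged in the `failed` column.
#'
#' @param series A [deviation_series()].
#' @param epochs,batch_sizes,hidden_units Lattice axes.
#' @param base_spec A [model_spec()] supplying all remaining settings.
#' @return Data frame of class `grid_search_result`, one row per cell,
#'   ranked; the winning cell first. Columns: `epochs`, `batch_size`,
#'   `hidden_units`, `mape`, `rmse`, `failed`, `rank`.
#' @export
grid_search <- function(series,
                        epochs = c(100, 300, 500, 700),
                        batch_sizes = c(128, 256),
                        hidden_units = c(32, 64),
                        base_spec = model_spec()) {
  cells <- expand.grid(epochs = epochs, batch_size = batch_sizes,
                       hidden_units = hidden_units)
  if (nrow(cells) == 0) stop("empty hyperparameter lattice", call. = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sp <- base_spec
    sp$epochs <- as.integer(cells$epochs[i])
    sp$batch_size <- as.integer(cells$batch_size[i])
    sp$hidden_units <- as.integer(cells$hidden_units[i])
    out <- tryCatch(fit_deviation_model(series, sp),
                    error = function(e) e)
    if (inherits(out, "error")) {
      data.frame(epochs = sp$epochs, batch_size = sp$batch_size,
                 hidden_units = sp$hidden_units,
                 mape = NA_real_, rmse = NA_real_, failed = TRUE)
    } else {
      data.frame(epochs = sp$epochs, batch_size = sp$batch_size,
                 hidden_units = sp$hidden_units,
                 mape = out$mape, rmse = out$rmse, failed = FALSE)
    }
  })
  tab <- do.call(rbind, res)
  ord <- order(tab$failed, tab$mape, tab$rmse, tab$epochs)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("grid_search_result", "data.frame")
  tab
}

#' Uniform compensation plan
#'
#' Distributes a predicted total (cumulative) deviation evenly over the
#' planned infusions: each commanded dose receives an add-on of
#' `predicted_total / n_infusions`. Conservation is exact.
#'
#' @param predicted_total_U Predicted cumulative deviation, U.
#' @param n_infusions Number of planned infusions (>= 1).
#' @return List of class `compensation_plan` with
#'   `predicted_total_deviation_U`, `n_infusions`,
#'   `per_infusion_compensation_U`.
#' @export
make_plan <- function(predicted_total_U, n_infusions) {
  if (n_infusions < 1) stop("`n_infusions` must be >= 1", call. = FALSE)
  structure(
    list(predicted_total_deviation_U = predicted_total_U,
         n_infusions = as.integer(n_infusions),
         per_infusion_compensation_U = predicted_total_U / n_infusions),
    class = "compensation_plan"
  )
}

#' @export
print.compensation_plan <- function(x, ...) {
  cat(sprintf(
    "Compensation plan: %.4f U total over %d infusions (%.5f U each)\n",
    x$predicted_total_deviation_U, x$n_infusions,
    x$per_infusion_compensation_U))
  invisible(x)
}

#' Apply a compensation plan to an infusion log
#'
#' Increments every commanded dose by the plan's per-infusion add-on.
#' Delivered doses are untouched — they must be re-simulated (e.g. with
#' [simulate_delivery()]) or re-measured downstream.
#'
#' @param log An [infusion_log()] with exactly `plan$n_infusions` records.
#' @param plan A [make_plan()] result.
#' @return The log with inflated commanded doses.
#' @export
apply_plan <- function(log, plan) {
  stopifnot(inherits(plan, "compensation_plan"))
  if (nrow(log) != plan$n_infusions) {
    stop("plan covers ", plan$n_infusions, " infusions but the log has ",
         nrow(log), call. = FALSE)
  }
  log$commanded_dose_U <- log$commanded_dose_U +
    plan$per_infusion_compensation_U
  log
}

#' Write a deviation series to CSV
#'
#' Columns: `infusion_index`, `commanded_dose_U`, `delivered_dose_U`,
#' `deviation_U`, `cumulative_deviation_U`.
#'
#' @param series A [deviation_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  df <- data.frame(
    infusion_index = seq_len(series$n),
    commanded_dose_U = series$commanded_dose_U,
    delivered_dose_U = series$commanded_dose_U -
      series$per_infusion_deviation_U,
    deviation_U = series$per_infusion_deviation_U,
    cumulative_deviation_U = series$cumulative_deviation_U
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a deviation series from CSV
#'
#' @param path CSV with at least `deviation_U` (or `commanded_dose_U` +
#'   `delivered_dose_U`) columns.
#' @return A [deviation_series()].
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  if ("deviation_U" %in% names(df)) {
    cmd <- if ("commanded_dose_U" %in% names(df)) df$commanded_dose_U[1] else NA
    deviation_series(df$deviation_U, commanded_dose_U = cmd)
  } else {
    deviation_series(infusion_log(df$commanded_dose_U, df$delivered_dose_U))
  }
}
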
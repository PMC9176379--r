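# Whole-body composition prediction from region-averaged optical fractions.

#' Fit the region-OFF/OLF whole-body composition model
#'
#' Linear (Gaussian, identity link) regression of a whole-body DXA
#' percentage on the optical fraction at the four anatomical regions:
#' OFF predicts fat\%, OLF predicts LST\%. Trained on a designated
#' training split only; predictors are on the percent (0-100) scale.
#'
#' @param regions data.frame of regional summaries (one row per
#'   participant x region) with columns \code{participant_id},
#'   \code{region}, \code{off}, \code{olf}
#' @param dxa data.frame with columns \code{participant_id},
#'   \code{fat_pct}, \code{lst_pct}
#' @param target \code{"fat_pct"} (predictor OFF) or \code{"lst_pct"}
#'   (predictor OLF)
#' @param train_ids participant ids to train on; default all shared ids.
#'   Use \code{split_cohort} to draw the 80/20 split.
#' @return object of class \code{bodycomp_model}: list with
#'   \code{target}, \code{predictor}, \code{intercept},
#'   \code{coefficients} (named by region), \code{train_ids}, \code{n},
#'   \code{sigma}
#' @export
fit_bodycomp <- function(regions, dxa, target = c("fat_pct", "lst_pct"),
                         train_ids = NULL) {
  target <- match.arg(target)
  predictor <- if (target == "fat_pct") "off" else "olf"
  wide <- regions_wide(regions, predictor)
  if (is.null(train_ids)) {
    train_ids <- intersect(wide$participant_id, dxa$participant_id)
  }
  missing_reg <- setdiff(train_ids, wide$participant_id)
  incomplete <- wide$participant_id[!stats::complete.cases(wide)]
  excluded <- union(missing_reg, intersect(train_ids, incomplete))
  if (length(excluded)) {
    stop("training participants lacking all four regions: ",
         paste(excluded, collapse = ", "), call. = FALSE)
  }
  missing_dxa <- setdiff(train_ids, dxa$participant_id)
  if (length(missing_dxa)) {
    stop("training participants lacking DXA records: ",
         paste(missing_dxa, collapse = ", "), call. = FALSE)
  }
  tr <- wide[match(train_ids, wide$participant_id), , drop = FALSE]
  tr$y <- dxa[[target]][match(train_ids, dxa$participant_id)]
  fit <- stats::lm(y ~ biceps + abdomen + quadriceps + calf, data = tr)
  cf <- stats::coef(fit)
  structure(list(target = target, predictor = predictor,
                 intercept = unname(cf[1]),
                 coefficients = cf[region_names],
                 train_ids = train_ids, n = length(train_ids),
                 sigma = stats::sigma(fit)),
            class = "bodycomp_model")
}

regions_wide <- function(regions, predictor) {
  need <- c("participant_id", "region", predictor)
  if (!all(need %in% names(regions))) {
    stop("regions table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  wide <- stats::reshape(
    regions[need], idvar = "participant_id", timevar = "region",
    direction = "wide")
  names(wide) <- sub(paste0("^", predictor, "\\."), "", names(wide))
  miss <- setdiff(region_names, names(wide))
  for (m in miss) wide[[m]] <- NA_real_
  wide
}

#' @export
print.bodycomp_model <- function(x, ...) {
  cat(sprintf("bodycomp model: %s ~ %s at 4 regions (n = %d)\n",
              x$target, toupper(x$predictor), x$n))
  print(c(intercept = x$intercept, x$coefficients))
  invisible(x)
}

#' Predict whole-body composition for participants
#'
#' @param model a \code{bodycomp_model}
#' @param regions regional summaries for the participants to predict; all
#'   four regions must be present for each
#' @return data.frame with \code{participant_id}, \code{prediction}
#'   (clamped to the reportable 0-100 range) and \code{out_of_range}
#' @export
predict_bodycomp <- function(model, regions) {
  stopifnot(inherits(model, "bodycomp_model"))
  wide <- regions_wide(regions, model$predictor)
  if (any(!stats::complete.cases(wide[region_names]))) {
    stop("every participant needs all four regions", call. = FALSE)
  }
  raw <- model$intercept +
    as.matrix(wide[region_names]) %*% model$coefficients
  raw <- as.numeric(raw)
  data.frame(participant_id = wide$participant_id,
             prediction = pmin(pmax(raw, 0), 100),
             out_of_range = raw < 0 | raw > 100)
}

#' Evaluate a body-composition model on held-out participants
#'
#' Applies the model to participants disjoint from its training split and
#' returns the Bland-Altman agreement of predictions against DXA. Any
#' overlap with the training ids raises a leakage error.
#'
#' @param model a \code{bodycomp_model}
#' @param regions regional summaries for the held-out participants
#' @param dxa DXA table covering the held-out participants
#' @param test_ids ids to evaluate; default all participants in
#'   \code{regions}
#' @return a \code{bland_altman} object (differences are predicted - DXA)
#' @export
evaluate_bodycomp <- function(model, regions, dxa, test_ids = NULL) {
  stopifnot(inherits(model, "bodycomp_model"))
  if (is.null(test_ids)) test_ids <- unique(regions$participant_id)
  leak <- intersect(test_ids, model$train_ids)
  if (length(leak)) {
    stop("evaluation would leak training participants: ",
         paste(leak, collapse = ", "), call. = FALSE)
  }
  sub <- regions[regions$participant_id %in% test_ids, , drop = FALSE]
  pred <- predict_bodycomp(model, sub)
  measured <- dxa[[model$target]][match(pred$participant_id,
                                        dxa$participant_id)]
  if (anyNA(measured)) {
    stop("missing DXA records for evaluation participants", call. = FALSE)
  }
  bland_altman(pred$prediction, measured)
}

#' Draw a train/test participant split
#'
#' Uniform random split with a recorded seed; the same split is intended
#' to be reused for the fat\% and LST\% models.
#'
#' @param ids participant ids
#' @param train_fraction fraction assigned to training (default 0.8)
#' @param seed integer seed
#' @return list with \code{train}, \code{test}, \code{seed}
#' @export
split_cohort <- function(ids, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  ids <- unique(ids)
  n_train <- round(train_fraction * length(ids))
  train <- withr::with_seed(seed, sample(ids, n_train))
  list(train = sort(train), test = sort(setdiff(ids, train)), seed = seed)
}
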
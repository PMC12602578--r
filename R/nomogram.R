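#' Radiomics score: weighted sum of selected features
#'
#' `r_score = F1*W1 + F2*W2 + ... + F10*W10`, with the weights taken from the
#' selector's importance scores for the selected features.
#'
#' @param table a `feature_table` containing every selected feature.
#' @param features feature_id character vector.
#' @param weights numeric weights, same length and order as `features`.
#' @return numeric r-score per sample.
#' @export
radiomics_score <- function(table, features, weights) {
  stopifnot(length(features) == length(weights))
  miss <- setdiff(features, colnames(table$values))
  if (length(miss))
    stop("feature(s) absent from the table: ", paste(miss, collapse = ", "))
  drop(table$values[, features, drop = FALSE] %*% weights)
}

#' Combined radiomics + clinical logistic model
#'
#' Maximum-likelihood logistic regression of pCR on the radiomics score and
#' the clinical covariates (ER, PR, HER2). Perfect or quasi-perfect
#' separation is detected and flagged; coefficients are still reported, with
#' a warning.
#'
#' @param r_score numeric radiomics score per sample.
#' @param clinical data.frame of clinical covariates (0/1 coded).
#' @param outcome 0/1 vector (1 = pCR).
#' @return a `nomogram_model`: `coef`, `se`, `fitted` (per-sample predicted
#'   probabilities), `separation` flag, predictor `ranges`, and the `glm`
#'   fit.
#' @export
fit_combined_model <- function(r_score, clinical, outcome) {
  stopifnot(nrow(clinical) == length(r_score),
            length(outcome) == length(r_score),
            all(outcome %in% 0:1))
  if (anyNA(r_score) || anyNA(clinical) || anyNA(outcome))
    stop("missing values are not allowed")
  df <- data.frame(r_score = r_score, clinical)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(outcome ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separation)
    warning("perfect or quasi-perfect separation detected; ",
            "coefficients are unstable")
  ranges <- vapply(df, range, numeric(2))
  structure(list(coef = stats::coef(fit),
                 se = summary(fit)$coefficients[, "Std. Error"],
                 fitted = stats::fitted(fit),
                 separation = separation,
                 ranges = ranges, fit = fit),
            class = "nomogram_model")
}

#' @export
print.nomogram_model <- function(x, ...) {
  cat("<nomogram_model> logistic model,", length(x$coef) - 1, "predictors",
      if (x$separation) "(separation flagged)", "\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' Export a points-based nomogram from a fitted combined model
#'
#' Each predictor is mapped to a points axis: the reference value (the end of
#' its observed range where the linear predictor is smallest) scores 0 points
#' and points accrue at `scale * coefficient` per unit, with the scale chosen
#' so the largest absolute effect spans exactly 100 points. Total points map
#' to predicted probability through the inverse logit of the affine
#' back-transform, so the points representation reproduces the logistic
#' model's probability exactly. Zero-range predictors are excluded with a
#' warning.
#'
#' @param model a `nomogram_model`.
#' @param json optional path: write the machine-readable nomogram table.
#' @param plot_file optional path: write a rendered figure (png).
#' @return a `nomogram` list: `vars` (per-variable point mapping), `scale`,
#'   `lp0` (linear predictor at all-reference values), `prob_axis`
#'   (total-points to probability ticks) and `plot` (a ggplot object).
#' @export
export_nomogram <- function(model, json = NULL, plot_file = NULL) {
  stopifnot(inherits(model, "nomogram_model"))
  beta <- model$coef[-1]
  rng <- model$ranges
  span <- abs(beta) * (rng[2, ] - rng[1, ])
  # NA coefficients (collinear/zero-range predictors dropped by glm) carry
  # no points
  span[is.na(beta)] <- 0
  drop_vars <- span == 0
  if (any(drop_vars)) {
    warning("zero-range predictor(s) excluded: ",
            paste(names(beta)[drop_vars], collapse = ", "))
    beta <- beta[!drop_vars]
    rng <- rng[, !drop_vars, drop = FALSE]
    span <- span[!drop_vars]
  }
  if (!length(beta)) {
    # intercept-only: a degenerate nomogram with constant probability
    nomo <- structure(list(vars = data.frame(variable = character(0),
                                             coef = numeric(0),
                                             min = numeric(0),
                                             max = numeric(0),
                                             ref = numeric(0),
                                             points_per_unit = numeric(0),
                                             max_points = numeric(0)),
                           scale = 1, lp0 = unname(model$coef[1]),
                           intercept = unname(model$coef[1]),
                           prob_axis = data.frame(
                             total_points = 0,
                             probability = stats::plogis(model$coef[1]))),
                      class = "nomogram")
    return(nomo)
  }
  s <- 100 / max(span)
  ref <- ifelse(beta > 0, rng[1, ], rng[2, ])
  vars <- data.frame(variable = names(beta), coef = unname(beta),
                     min = rng[1, ], max = rng[2, ], ref = unname(ref),
                     points_per_unit = unname(s * beta),
                     max_points = unname(s * span), row.names = NULL)
  lp0 <- unname(model$coef[1] + sum(beta * ref))
  total_range <- c(0, sum(vars$max_points))
  ticks <- pretty(total_range, 8)
  ticks <- ticks[ticks >= total_range[1] & ticks <= total_range[2]]
  prob_axis <- data.frame(total_points = ticks,
                          probability = stats::plogis(lp0 + ticks / s))
  nomo <- structure(list(vars = vars, scale = s, lp0 = lp0,
                         intercept = unname(model$coef[1]),
                         prob_axis = prob_axis),
                    class = "nomogram")
  nomo$plot <- plot_nomogram(nomo)
  if (!is.null(json))
    jsonlite::write_json(nomo[c("vars", "scale", "lp0", "intercept",
                                "prob_axis")],
                         json, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
  if (!is.null(plot_file)) {
    ggplot2::ggsave(plot_file, nomo$plot, width = 7, height = 1 +
                      0.8 * (nrow(vars) + 2), dpi = 150, limitsize = FALSE)
  }
  nomo
}

#' Total points and predicted probability for new samples
#'
#' @param nomo a `nomogram`.
#' @param data data.frame containing every nomogram variable.
#' @return data.frame with per-variable points, `total_points` and
#'   `probability`.
#' @export
nomogram_points <- function(nomo, data) {
  miss <- setdiff(nomo$vars$variable, names(data))
  if (length(miss))
    stop("variable(s) absent from data: ", paste(miss, collapse = ", "))
  if (!nrow(nomo$vars)) {
    return(data.frame(total_points = rep(0, nrow(data)),
                      probability = stats::plogis(rep(nomo$lp0, nrow(data)))))
  }
  pts <- sapply(seq_len(nrow(nomo$vars)), function(i) {
    v <- nomo$vars[i, ]
    v$points_per_unit * (data[[v$variable]] - v$ref)
  })
  pts <- matrix(pts, nrow = nrow(data),
                dimnames = list(NULL, nomo$vars$variable))
  total <- rowSums(pts)
  out <- data.frame(pts, check.names = FALSE)
  out$total_points <- total
  out$probability <- stats::plogis(nomo$lp0 + total / nomo$scale)
  out
}

# axis-per-variable rendering: one points ruler on top, one row per
# predictor, then the total-points and probability axes
plot_nomogram <- function(nomo) {
  vars <- nomo$vars
  n <- nrow(vars)
  rows <- list()
  for (i in seq_len(n)) {
    v <- vars[i, ]
    ticks <- pretty(c(v$min, v$max), 5)
    ticks <- ticks[ticks >= v$min & ticks <= v$max]
    pos <- v$points_per_unit * (ticks - v$ref)
    rows[[i]] <- data.frame(axis = v$variable, y = n - i + 1,
                            x = pos, label = format(ticks))
  }
  tick_df <- do.call(rbind, rows)
  pts_ticks <- pretty(c(0, 100), 10)
  top <- data.frame(axis = "Points", y = n + 1, x = pts_ticks,
                    label = format(pts_ticks))
  tot <- data.frame(axis = "Total points", y = 0,
                    x = nomo$prob_axis$total_points,
                    label = format(nomo$prob_axis$total_points))
  prob <- data.frame(axis = "Probability of pCR", y = -1,
                     x = nomo$prob_axis$total_points,
                     label = sprintf("%.2f", nomo$prob_axis$probability))
  df <- rbind(top, tick_df, tot, prob)
  seg <- do.call(rbind, lapply(split(df, df$y), function(d)
    data.frame(y = d$y[1], x0 = min(d$x), x1 = max(d$x), axis = d$axis[1])))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, xend = .data$x1,
                                       y = .data$y, yend = .data$y)) +
    ggplot2::geom_point(data = df, ggplot2::aes(x = .data$x, y = .data$y),
                        shape = 3, size = 2) +
    ggplot2::geom_text(data = df,
                       ggplot2::aes(x = .data$x, y = .data$y + 0.25,
                                    label = .data$label), size = 2.8) +
    ggplot2::scale_y_continuous(breaks = sort(unique(df$y)),
                                labels = seg$axis[order(seg$y)]) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Radiomics + clinical nomogram") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}
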
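#' Fit a two-class Fisher linear discriminant
#'
#' Computes the projection direction maximizing the Fisher criterion
#' \deqn{J(w) = \frac{(w^T\mu_1 - w^T\mu_2)^2}{w^T d_w w},}
#' where \eqn{d_w = d_1 + d_2} is the pooled within-class scatter (sum of
#' outer products of centered rows).  The optimum is the closed form
#' \eqn{w = d_w^{-1}(\mu_1 - \mu_2)}.  The decision threshold is the midpoint
#' of the projected class means, \eqn{t = (w^T\mu_1 + w^T\mu_2)/2}, treating
#' the classes with equal priors.  `w` is oriented so the first class
#' projects above the second.
#'
#' When `d_w` is ill-conditioned it is ridge-regularized by
#' `lambda * trace(d_w)/d` on the diagonal before inversion (short recordings
#' with 24-dimensional features can be rank-deficient).
#'
#' @param x1 `n1 x d` matrix of class-1 feature vectors (`n1 >= 2`).
#' @param x2 `n2 x d` matrix of class-2 feature vectors (`n2 >= 2`).
#' @param labels length-2 character vector naming the classes.
#' @param lambda ridge factor used when `d_w` is numerically singular.
#' @return An object of class `frcc_lda`: list with `w`, `threshold`, `mu1`,
#'   `mu2`, `labels`, `n`, `J` (the attained Fisher criterion).
#' @examples
#' set.seed(1)
#' x1 <- matrix(rnorm(100, 1), ncol = 2)
#' x2 <- matrix(rnorm(100, -1), ncol = 2)
#' m <- lda_fit(x1, x2)
#' lda_decide(lda_project(c(1, 1), m), m)
#' @export
lda_fit <- function(x1, x2, labels = c("omega1", "omega2"), lambda = 1e-8) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (nrow(x1) < 2 || nrow(x2) < 2) {
    rlang::abort("each class needs at least 2 observations", class = "frcc_insufficient_data")
  }
  if (ncol(x1) != ncol(x2)) rlang::abort("dimension mismatch", class = "frcc_invalid_input")
  d <- ncol(x1)
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  dm <- mu1 - mu2
  if (sqrt(sum(dm^2)) < 1e-12 * (1 + sqrt(sum(mu1^2)))) {
    rlang::abort("class means coincide: no discriminant direction exists",
                 class = "frcc_degenerate_direction")
  }
  dw <- crossprod(sweep(x1, 2, mu1)) + crossprod(sweep(x2, 2, mu2))
  w <- tryCatch(solve(dw, dm), error = function(e) NULL)
  if (is.null(w) || rcond(dw) < 1e-12) {
    dwr <- dw + diag(lambda * sum(diag(dw)) / d, d)
    w <- tryCatch(solve(dwr, dm), error = function(e) {
      rlang::abort("within-class scatter singular even after regularization",
                   class = "frcc_singular_scatter")
    })
  }
  w <- as.numeric(w)
  if (sum(w * dm) < 0) w <- -w  # orient: class 1 projects high
  J <- (sum(w * dm))^2 / drop(t(w) %*% dw %*% w)
  structure(list(w = w, threshold = (sum(w * mu1) + sum(w * mu2)) / 2,
                 mu1 = mu1, mu2 = mu2, labels = labels,
                 n = c(nrow(x1), nrow(x2)), J = J,
                 dims = colnames(x1) %||% sprintf("x%d", seq_len(d))),
            class = "frcc_lda")
}

#' Project feature vectors onto the discriminant axis
#'
#' The scalar score `y = w' x`, linear in `x`.
#'
#' @param x numeric vector of length `d`, or an `n x d` matrix.
#' @param model a fitted [lda_fit()] object.
#' @return Numeric score(s).
#' @export
lda_project <- function(x, model) {
  if (is.matrix(x)) {
    if (ncol(x) != length(model$w)) rlang::abort("dimension mismatch", class = "frcc_invalid_input")
    return(drop(x %*% model$w))
  }
  if (length(x) != length(model$w)) rlang::abort("dimension mismatch", class = "frcc_invalid_input")
  sum(x * model$w)
}

#' Threshold decision on a projected score
#'
#' Scores at or above the threshold are assigned to the first class,
#' below it to the second (`y >= t` selects class 1).
#'
#' @param y numeric score(s) from [lda_project()].
#' @param model a fitted [lda_fit()] object.
#' @return Character vector of class labels.
#' @export
lda_decide <- function(y, model) {
  ifelse(y >= model$threshold, model$labels[1], model$labels[2])
}

#' @export
#' @param object a fitted `frcc_lda` model.
#' @param newdata numeric vector or matrix of feature vectors.
#' @param type `"class"` for labels, `"score"` for projections.
#' @param ... unused.
#' @rdname lda_fit
predict.frcc_lda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  y <- lda_project(newdata, object)
  if (type == "score") y else lda_decide(y, object)
}

#' @method print frcc_lda
#' @export
print.frcc_lda <- function(x, ...) {
  cat(sprintf("<frcc_lda> d = %d, n = %d + %d, J = %.4g, threshold = %.4g\n",
              length(x$w), x$n[1], x$n[2], x$J, x$threshold))
  invisible(x)
}

#' @method tidy frcc_lda
#' @export
tidy.frcc_lda <- function(x, ...) {
  tibble::tibble(term = x$dims, estimate = x$w,
                 mean_class1 = x$mu1, mean_class2 = x$mu2)
}

#' @method glance frcc_lda
#' @export
glance.frcc_lda <- function(x, ...) {
  tibble::tibble(J = x$J, threshold = x$threshold,
                 n1 = x$n[1], n2 = x$n[2], d = length(x$w))
}
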
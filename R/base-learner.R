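#' Regularized logistic base learner
#'
#' The default base classifier behind the label-powerset ensemble and the
#' classifier chain. Binary responses are fitted with ridge-regularized
#' logistic regression at a fixed penalty (deterministic, fast on
#' topic-proportion or embedding features); multiclass responses (the
#' label-powerset transformation) with weight-decayed multinomial
#' regression, which tolerates the singleton classes rare label
#' combinations produce. Degenerate responses — a single class, or a
#' binary class with fewer than two observations — yield a constant
#' predictor at the empirical class rate.
#'
#' @param lambda ridge penalty for the binary fits; also used as weight
#'   decay in the multinomial fits.
#' @return a base learner: list with `fit(X, y)` and
#'   `predict(fit, X, type = c("class", "prob"))` where `prob` is the
#'   positive-class probability (binary) or a class-probability matrix.
#' @export
make_logistic_learner <- function(lambda = 1e-2) {
  pad <- function(X) {
    X <- as.matrix(X)
    if (ncol(X) < 2L) cbind(X, `.pad` = 0) else X
  }
  list(
    fit = function(X, y) {
      y <- factor(y)
      counts <- table(y)
      if (nlevels(y) < 2L)
        return(structure(list(constant = levels(y)[1], prob = 1),
                         class = "constant_fit"))
      if (nlevels(y) == 2L) {
        if (min(counts) < 2L) {
          pos_rate <- mean(y == levels(y)[2])
          return(structure(list(constant = levels(y)[which.max(counts)],
                                prob = pos_rate),
                           class = "constant_fit"))
        }
        fit <- glmnet::glmnet(pad(X), y, family = "binomial", alpha = 0,
                              lambda = lambda, standardize = FALSE)
        return(structure(list(fit = fit, levels = levels(y),
                              family = "binomial"),
                         class = "glmnet_fit"))
      }
      fit <- nnet::multinom(y ~ ., data = data.frame(y = y, pad(X)),
                            decay = lambda, maxit = 200, trace = FALSE,
                            MaxNWts = 100000)
      structure(list(fit = fit, levels = levels(y), family = "multinomial"),
                class = "multinom_fit")
    },
    predict = function(obj, X, type = c("class", "prob")) {
      type <- match.arg(type)
      X <- pad(X)
      if (inherits(obj, "constant_fit")) {
        if (type == "class") return(rep(obj$constant, nrow(X)))
        return(rep(obj$prob, nrow(X)))
      }
      if (inherits(obj, "multinom_fit")) {
        if (type == "class")
          return(as.character(stats::predict(obj$fit,
                                             newdata = data.frame(X),
                                             type = "class")))
        pr <- stats::predict(obj$fit, newdata = data.frame(X),
                             type = "probs")
        if (is.null(dim(pr)))  # two-class multinom returns a vector
          pr <- cbind(1 - pr, pr)
        colnames(pr) <- obj$levels
        return(pr)
      }
      if (type == "class") {
        as.character(stats::predict(obj$fit, X, type = "class"))
      } else {
        as.numeric(stats::predict(obj$fit, X, type = "response"))
      }
    }
  )
}
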
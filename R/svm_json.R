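# Portable model persistence. The exported JSON stores the support
# vectors, dual coefficients and offsets of each one-vs-one machine plus
# the feature-scaling parameters; the restored model predicts through an
# explicit implementation of the kernel decision function
#   f(x) = sgn( sum_i y_i a_i* k(x_i, x) + b* ),
# which doubles as an independent check on the fitted classifier.

#' Export a trained SVM to JSON
#'
#' @param model A `wpse_svm` from [svm_train()] (RBF kernel only).
#' @param path Optional file path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
svm_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "wpse_svm"))
  if (model$kernel != "rbf") {
    stop("JSON export supports the rbf kernel only", call. = FALSE)
  }
  fit <- model$fit
  payload <- list(
    kernel = model$kernel, C = model$C, gamma = model$gamma,
    classes = model$classes, bands = model$bands,
    center = unname(model$center), scale = unname(model$scale),
    sv = unname(as.matrix(fit$SV)), coefs = unname(as.matrix(fit$coefs)),
    rho = as.numeric(fit$rho), n_sv = as.integer(fit$nSV),
    labels = as.integer(fit$labels)
  )
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Restore an SVM from its JSON export
#'
#' @param json JSON string or path to a file written by [svm_to_json()].
#' @return A `wpse_svm_restored` model whose [predict()] method evaluates
#'   the stored decision functions directly.
#' @export
svm_from_json <- function(json) {
  p <- jsonlite::fromJSON(json)
  structure(list(kernel = p$kernel, C = p$C, gamma = p$gamma,
                 classes = p$classes, bands = p$bands,
                 center = setNames(p$center, p$bands),
                 scale = setNames(p$scale, p$bands),
                 sv = as.matrix(p$sv), coefs = as.matrix(p$coefs),
                 rho = as.numeric(p$rho), n_sv = as.integer(p$n_sv),
                 labels = as.integer(p$labels)),
            class = "wpse_svm_restored")
}

#' @export
predict.wpse_svm_restored <- function(object, newdata, ...) {
  x <- .svm_matrix(newdata, object$bands)
  xs <- scale(x, center = object$center, scale = object$scale)
  k <- length(object$n_sv)                       # number of classes
  sv <- object$sv
  # RBF kernel between every probe row and every support vector
  d2 <- outer(rowSums(xs^2), rowSums(sv^2), "+") - 2 * xs %*% t(sv)
  K <- exp(-object$gamma * pmax(d2, 0))
  start <- c(0L, cumsum(object$n_sv))            # SV block per class
  votes <- matrix(0L, nrow(xs), k)
  pair <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      pair <- pair + 1L
      idx_i <- (start[i] + 1L):start[i + 1L]
      idx_j <- (start[j] + 1L):start[j + 1L]
      dec <- K[, idx_i, drop = FALSE] %*% object$coefs[idx_i, j - 1L] +
        K[, idx_j, drop = FALSE] %*% object$coefs[idx_j, i] -
        object$rho[pair]
      winner <- ifelse(dec > 0, i, j)
      for (w in c(i, j)) {
        votes[, w] <- votes[, w] + (winner == w)
      }
    }
  }
  # class order in the model is fit$labels, an index into `classes`
  cls <- object$classes[object$labels]
  factor(cls[apply(votes, 1L, which.max)], levels = object$classes)
}
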
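# RBF-kernel C-SVM trained with a deterministic SMO solver.
#
# The solver is Platt's sequential minimal optimisation with an error cache
# and the usual examine-all / non-bound alternation, but with fully
# deterministic index ordering (no random pair selection), so identical
# inputs give identical models. Problem sizes here are small (tens to a few
# hundred samples), well within SMO's comfort zone.

.rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# y in {-1, +1}; returns alpha, b and support info
.smo_solve <- function(K, y, C, tol = 1e-3, eps = 1e-8, max_passes = 200L) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  fcache <- numeric(n)            # f(x_i) with current alpha, b
  errs <- function() fcache - y

  take_step <- function(i1, i2) {
    if (i1 == i2) return(FALSE)
    a1 <- alpha[i1]; a2 <- alpha[i2]
    y1 <- y[i1]; y2 <- y[i2]
    E1 <- fcache[i1] - y1; E2 <- fcache[i2] - y2
    s <- y1 * y2
    if (s > 0) { L <- max(0, a1 + a2 - C); H <- min(C, a1 + a2) }
    else       { L <- max(0, a2 - a1);     H <- min(C, C + a2 - a1) }
    if (L >= H - eps) return(FALSE)
    k11 <- K[i1, i1]; k12 <- K[i1, i2]; k22 <- K[i2, i2]
    eta <- k11 + k22 - 2 * k12
    if (eta > eps) {
      a2new <- a2 + y2 * (E1 - E2) / eta
      a2new <- min(max(a2new, L), H)
    } else {
      # objective at the two ends (rare with RBF); pick the better end
      f1 <- y1 * (E1 + b) - a1 * k11 - s * a2 * k12
      f2 <- y2 * (E2 + b) - s * a1 * k12 - a2 * k22
      L1 <- a1 + s * (a2 - L); H1 <- a1 + s * (a2 - H)
      psiL <- L1 * f1 + L * f2 + 0.5 * L1^2 * k11 + 0.5 * L^2 * k22 + s * L * L1 * k12
      psiH <- H1 * f1 + H * f2 + 0.5 * H1^2 * k11 + 0.5 * H^2 * k22 + s * H * H1 * k12
      a2new <- if (psiL < psiH - eps) L else if (psiH < psiL - eps) H else a2
    }
    if (abs(a2new - a2) < eps * (a2new + a2 + eps)) return(FALSE)
    a1new <- a1 + s * (a2 - a2new)
    # threshold update
    b1 <- E1 + y1 * (a1new - a1) * k11 + y2 * (a2new - a2) * k12 + b
    b2 <- E2 + y1 * (a1new - a1) * k12 + y2 * (a2new - a2) * k22 + b
    bnew <- if (a1new > eps && a1new < C - eps) b1
            else if (a2new > eps && a2new < C - eps) b2
            else (b1 + b2) / 2
    dc <- bnew - b
    fcache <<- fcache + y1 * (a1new - a1) * K[, i1] +
      y2 * (a2new - a2) * K[, i2] - dc
    # note: f = sum alpha y K - b convention; see decision_values below
    alpha[i1] <<- a1new
    alpha[i2] <<- a2new
    b <<- bnew
    TRUE
  }

  examine <- function(i2) {
    y2 <- y[i2]; a2 <- alpha[i2]
    E2 <- fcache[i2] - y2
    r2 <- E2 * y2
    if ((r2 < -tol && a2 < C - eps) || (r2 > tol && a2 > eps)) {
      nb <- which(alpha > eps & alpha < C - eps)
      if (length(nb) > 1L) {
        E <- fcache - y
        i1 <- nb[which.max(abs(E[nb] - E2))]
        if (take_step(i1, i2)) return(TRUE)
      }
      for (i1 in c(nb, seq_len(n))) if (take_step(i1, i2)) return(TRUE)
    }
    FALSE
  }

  examine_all <- TRUE
  passes <- 0L
  repeat {
    changed <- 0L
    idx <- if (examine_all) seq_len(n) else which(alpha > eps & alpha < C - eps)
    for (i in idx) changed <- changed + examine(i)
    passes <- passes + 1L
    if (passes > max_passes) break
    if (examine_all) {
      if (changed == 0L) break
      examine_all <- FALSE
    } else if (changed == 0L) {
      examine_all <- TRUE
    }
  }
  list(alpha = alpha, b = b)
}

#' Train an RBF-kernel SVM
#'
#' Features are standardized with the training-set mean and SD (stored with
#' the model); constant columns are dropped with a warning. The positive
#' class is `"ischemic"` when present, otherwise the second factor level.
#'
#' @param X numeric feature matrix (named columns), no missing values.
#' @param y class labels (two classes required).
#' @param cfg a [model_config()].
#' @return An `ischemia_svm` model object.
#' @export
train_svm <- function(X, y, cfg = model_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing values in the feature matrix", call. = FALSE)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("need two classes to train", call. = FALSE)
  y <- droplevels(y)
  pos <- if ("ischemic" %in% levels(y)) "ischemic" else levels(y)[2]
  yv <- ifelse(y == pos, 1, -1)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  const <- scl == 0
  if (any(const)) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(colnames(X)[const], collapse = ", ")), call. = FALSE)
    X <- X[, !const, drop = FALSE]
    ctr <- ctr[!const]; scl <- scl[!const]
  }
  if (ncol(X) == 0L) stop("no usable features after dropping constants", call. = FALSE)
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  gamma <- cfg$gamma
  if (is.null(gamma)) {
    v <- var(as.numeric(Z))
    gamma <- 1 / (ncol(Z) * if (v > 0) v else 1)
  }
  K <- .rbf_kernel(Z, Z, gamma)
  fit <- .smo_solve(K, yv, C = cfg$C)
  structure(list(Z = Z, yv = yv, alpha = fit$alpha, b = fit$b, gamma = gamma,
                 center = ctr, scale = scl, features = colnames(X),
                 positive = pos, levels = levels(y), C = cfg$C),
            class = "ischemia_svm")
}

#' Decision scores and predicted labels
#'
#' @param object an `ischemia_svm` model.
#' @param newdata numeric matrix with the model's feature columns.
#' @param type `"score"` for continuous decision values (positive favours the
#'   positive class) or `"label"` for class labels.
#' @param ... unused.
#' @return Numeric scores or a character vector of labels.
#' @export
predict.ischemia_svm <- function(object, newdata, type = c("score", "label"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    missing <- setdiff(object$features, colnames(newdata))
    if (length(missing)) {
      stop(sprintf("missing feature column(s): %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    newdata <- newdata[, object$features, drop = FALSE]
  }
  Z <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  Kt <- .rbf_kernel(Z, object$Z, object$gamma)
  f <- as.numeric(Kt %*% (object$alpha * object$yv)) - object$b
  if (type == "score") return(f)
  neg <- setdiff(object$levels, object$positive)[1]
  ifelse(f >= 0, object$positive, neg)
}
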
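#' K-means cluster-number scan with BIC
#'
#' Mean-imputes missing calls, runs PCA on the centred dosage matrix and
#' K-means (multiple starts) for K = 1..`k_max` on the retained principal
#' components, scoring each K with BIC = n log(WSS/n) + K log(n). The
#' best-supported number of clusters minimises BIC.
#'
#' @param panel A `genotype_panel`.
#' @param k_max Largest K (default 10).
#' @param n_pcs Retained principal components (default: all up to 100;
#'   clipped to the matrix rank with a warning).
#' @param n_start K-means restarts per K (default 20).
#' @param seed Integer seed.
#' @return List with `scan` (data frame K, WSS, BIC), `best_k`,
#'   `clusters` (assignment at `best_k`), `pcs` (the retained scores).
#' @export
kmeans_bic <- function(panel, k_max = 10L, n_pcs = NULL, n_start = 20L,
                       seed = 1L) {
  m <- impute_mean(panel$calls)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-9)
  if (is.null(n_pcs)) n_pcs <- min(100L, rank)
  if (n_pcs > rank) {
    warning("n_pcs reduced to the matrix rank (", rank, ")")
    n_pcs <- rank
  }
  x <- pc$x[, seq_len(n_pcs), drop = FALSE]
  n <- nrow(x)
  n_distinct <- nrow(unique(round(x, 8)))
  set.seed(seed)
  rows <- lapply(seq_len(min(k_max, n - 1, n_distinct)), function(k) {
    if (k == 1) {
      wss <- sum(scale(x, scale = FALSE)^2)
      cl <- rep(1L, n)
    } else {
      km <- stats::kmeans(x, k, nstart = n_start, iter.max = 100)
      wss <- km$tot.withinss
      cl <- km$cluster
    }
    list(row = data.frame(K = k, WSS = wss,
                          BIC = n * log(wss / n) + k * log(n)),
         clusters = cl)
  })
  scan <- do.call(rbind, lapply(rows, `[[`, "row"))
  best <- which.min(scan$BIC)
  list(scan = scan, best_k = scan$K[best],
       clusters = rows[[best]]$clusters, pcs = x,
       center = pc$center, rotation = pc$rotation[, seq_len(n_pcs),
                                                  drop = FALSE])
}

impute_mean <- function(m) {
  for (j in seq_len(ncol(m))) {
    mj <- m[, j]
    if (anyNA(mj)) mj[is.na(mj)] <- mean(mj, na.rm = TRUE)
    m[, j] <- mj
  }
  storage.mode(m) <- "double"
  m
}

#' Discriminant analysis of principal components
#'
#' Linear discriminant analysis on retained principal components of the
#' mean-imputed dosage matrix, with the number of components chosen by
#' stratified cross-validation over a grid (the retained count with the
#' highest held-out assignment accuracy, smallest on ties) unless fixed.
#'
#' @param panel A `genotype_panel`.
#' @param clusters Cluster assignment per individual (factor or integer;
#'   e.g. from [kmeans_bic()]). Every cluster needs >= 2 members.
#' @param n_pcs `"cv"` (default) for cross-validated choice, or an
#'   integer.
#' @param seed Integer seed for the cross-validation folds.
#' @return Object of class `dapc_fit`: posterior membership matrix
#'   (`posterior`), assignments, PC scores used, the LDA fit, the chosen
#'   `n_pcs`, and the centring/rotation needed to project new data.
#' @export
dapc_assign <- function(panel, clusters, n_pcs = "cv", seed = 1L) {
  cl <- factor(clusters)
  if (any(table(cl) < 2))
    stop("cluster with fewer than 2 members: ",
         paste(names(which(table(cl) < 2)), collapse = ", "))
  m <- impute_mean(panel$calls)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-9)
  n <- nrow(m)
  max_pc <- min(rank, n - nlevels(cl) - 1)
  if (identical(n_pcs, "cv")) {
    grid <- unique(pmin(c(5L, 10L, 20L, 40L, 80L), max_pc))
    set.seed(seed)
    folds <- make_folds(cl, 5L)
    acc <- vapply(grid, function(np) {
      x <- pc$x[, seq_len(np), drop = FALSE]
      correct <- 0L
      for (f in seq_along(folds)) {
        test <- folds[[f]]
        fit <- MASS::lda(x[-test, , drop = FALSE], cl[-test])
        pr <- stats::predict(fit, x[test, , drop = FALSE])$class
        correct <- correct + sum(pr == cl[test])
      }
      correct / n
    }, 0)
    n_pcs <- grid[which.max(acc)]
  }
  n_pcs <- min(n_pcs, max_pc)
  x <- pc$x[, seq_len(n_pcs), drop = FALSE]
  fit <- MASS::lda(x, cl)
  pr <- stats::predict(fit, x)
  structure(list(posterior = pr$posterior, assignment = pr$class,
                 scores = x, lda = fit, n_pcs = n_pcs,
                 center = pc$center,
                 rotation = pc$rotation[, seq_len(n_pcs), drop = FALSE],
                 clusters = cl),
            class = "dapc_fit")
}

make_folds <- function(cl, k) {
  # stratified: deal members of each class round-robin into k folds
  folds <- vector("list", k)
  for (cls in split(seq_along(cl), cl)) {
    cls <- sample(cls)
    for (i in seq_along(cls)) {
      f <- (i - 1L) %% k + 1L
      folds[[f]] <- c(folds[[f]], cls[i])
    }
  }
  Filter(length, folds)
}

#' @export
print.dapc_fit <- function(x, ...) {
  cat("dapc_fit:", nlevels(x$clusters), "clusters,", x$n_pcs,
      "PCs retained\n")
  cat("min own-cluster posterior:",
      format(min(x$posterior[cbind(seq_len(nrow(x$posterior)),
                                   as.integer(x$assignment))])), "\n")
  invisible(x)
}

#' Project new genotypes onto a DAPC fit
#'
#' @param object A `dapc_fit`.
#' @param newdata A `genotype_panel` (same loci as the training panel).
#' @param ... Ignored.
#' @return List with `scores` (PC coordinates) and `posterior`.
#' @export
predict.dapc_fit <- function(object, newdata, ...) {
  m <- impute_mean(newdata$calls)
  x <- scale(m, center = object$center, scale = FALSE) %*% object$rotation
  pr <- stats::predict(object$lda, x)
  list(scores = x, posterior = pr$posterior, assignment = pr$class)
}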
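# Bagged HABiC: B naive classifiers, each fitted on a stratified bootstrap
# (n/2 draws with replacement per class, preserving the exact balance the
# assignment solve requires) and a random feature subset of size mtry
# (default floor(sqrt(p))). The rf/pls flavours rank the drawn features by
# random-forest or PLS-DA importance and keep only the top n_keep (or the
# smallest prefix reaching importance_fraction of the total importance).
fit_bagged_model <- function(x, yf, filter, B, mtry, n_keep,
                             importance_fraction, q, threshold, seed,
                             ncomp_pls, chunk_size) {
  lv <- levels(yf)
  i0 <- which(yf == lv[1L])
  i1 <- which(yf == lv[2L])
  stopifnot(length(i0) == length(i1))
  n0 <- length(i0)
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  mtry <- min(as.integer(mtry), p)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  if (filter != "none" && is.null(importance_fraction) && n_keep > mtry) {
    warning(sprintf("n_keep = %d exceeds the %d drawn features; clipped",
                    n_keep, mtry), call. = FALSE)
    n_keep <- mtry
  }
  seeds <- child_seeds(seed, B)
  members <- lapply(seq_len(B), function(b) {
    draw <- with_seed(seeds[b], {
      list(r0 = sample(i0, n0, replace = TRUE),
           r1 = sample(i1, n0, replace = TRUE),
           feats = sort(sample.int(p, mtry)),
           sub_seeds = sample.int(2147483646L, 2L))
    })
    rows <- c(draw$r0, draw$r1)
    feats <- draw$feats
    xb <- x[rows, feats, drop = FALSE]
    yb <- yf[rows]
    if (filter != "none") {
      imp <- if (filter == "rf")
        rf_importance(xb, yb, seed = draw$sub_seeds[1L])
      else
        plsda_importance(xb, yb, ncomp = ncomp_pls)
      ord <- order(imp, decreasing = TRUE)
      kept_local <- if (!is.null(importance_fraction)) {
        tot <- sum(imp)
        if (tot <= 0) seq_along(feats)
        else ord[seq_len(which(cumsum(imp[ord]) >= importance_fraction * tot)[1L])]
      } else {
        ord[seq_len(n_keep)]
      }
      kept_local <- sort(kept_local)
      feats <- feats[kept_local]
      xb <- xb[, kept_local, drop = FALSE]
    }
    fit <- fit_kr_model(xb, yb, q = q, threshold = threshold,
                        seed = draw$sub_seeds[2L], chunk_size = chunk_size)
    list(features = feats, rows = rows, fit = fit)
  })
  list(members = members, B = B, mtry = mtry, filter = filter,
       n_keep = if (filter == "none") NA_integer_ else n_keep,
       importance_fraction = importance_fraction,
       member_seeds = seeds, chunk_size = chunk_size)
}

# Majority vote over members, each voting on its own feature subset.
# Exact vote ties are broken by the sign of the summed member margins
# (g-hat minus alpha, orientation-signed toward the second level).
predict_bagged <- function(object, newdata, type) {
  lv <- object$levels
  if (type %in% c("score", "components"))
    stop(sprintf("type '%s' is not available for bagged models; use 'margin'",
                 type), call. = FALSE)
  m <- nrow(newdata)
  votes <- numeric(m)     # votes for lv[2]
  marg <- numeric(m)      # summed signed margins toward lv[2]
  for (mem in object$members) {
    fit <- mem$fit
    g <- predict(fit$optimizer, newdata[, mem$features, drop = FALSE],
                 chunk_size = object$chunk_size)
    high_is_2 <- fit$high_class == lv[2L]
    s <- (g - fit$alpha) * if (high_is_2) 1 else -1
    # member votes its predicted class: high class iff g > alpha
    votes <- votes + if (high_is_2) (g > fit$alpha) else !(g > fit$alpha)
    marg <- marg + s
  }
  if (type == "margin") return(marg / object$B)
  half <- object$B / 2
  pred <- ifelse(votes > half, lv[2L],
                 ifelse(votes < half, lv[1L],
                        ifelse(marg > 0, lv[2L], lv[1L])))
  factor(pred, levels = lv)
}
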
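.sigmoid <- function(z) 1 / (1 + exp(-z))

.softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

.mlpForward <- function(clf, X) {
  H1 <- .sigmoid(sweep(X %*% clf$W1, 2L, clf$b1, "+"))
  H2 <- .sigmoid(sweep(H1 %*% clf$W2, 2L, clf$b2, "+"))
  O <- .softmaxRows(sweep(H2 %*% clf$W3, 2L, clf$b3, "+"))
  list(H1 = H1, H2 = H2, O = O)
}

#' Train the per-electrode feedforward classifier
#'
#' Fits a two-class feedforward network (input of \code{ncol(X)} features,
#' two sigmoid hidden layers, two-unit output normalized to class
#' probabilities) by full-batch Adam on the cross-entropy loss, with early
#' stopping on a held-out validation split. Features are z-scored with
#' statistics estimated on the training portion, and the statistics are
#' stored in the model so that normalization is applied exactly once at
#' prediction time. Training is deterministic given \code{seed}.
#'
#' @param X numeric matrix, windows x features (M * P columns).
#' @param y character vector of labels, \code{"pregrooming"} or
#'   \code{"other"}; both classes must be present.
#' @param seed integer RNG seed (initialization and validation split).
#' @param hidden two hidden-layer widths; default \code{c(16, 8)}.
#' @param epochs maximum training epochs; default 300.
#' @param lr Adam learning rate; default 0.01.
#' @param valFraction validation fraction for early stopping; default 0.2.
#' @param patience epochs without validation improvement before stopping;
#'   default 30.
#' @param nStarts number of seeded restarts; the fit with the lowest
#'   validation loss is kept (small networks on small samples occasionally
#'   stall in a one-class minimum); default 3.
#' @param channelId electrode label stored in the model.
#' @return an \linkS4class{ElectrodeClassifier}.
#' @export
trainElectrodeClassifier <- function(X, y, seed = 1L, hidden = c(16L, 8L),
                                     epochs = 300L, lr = 0.01,
                                     valFraction = 0.2, patience = 30L,
                                     nStarts = 3L, channelId = "ch") {
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L)
    stop("single-class training set: both classes must be present")
  if (!all(y %in% c("pregrooming", "other")))
    stop("labels must be 'pregrooming' or 'other'")
  fits <- lapply(seq_len(nStarts), function(k)
    .fitMlp(X, y, .childSeed(seed, k - 1L), hidden, epochs, lr, valFraction,
            patience))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "valLoss"))]]
  par <- lapply(best$par, unname)
  new("ElectrodeClassifier", W1 = par$W1, b1 = par$b1, W2 = par$W2,
      b2 = par$b2, W3 = par$W3, b3 = par$b3, featMean = best$mu,
      featSd = best$sdv, channelId = as.character(channelId),
      seed = as.integer(seed), epochsRun = as.integer(best$epochs))
}

.fitMlp <- function(X, y, seed, hidden, epochs, lr, valFraction, patience) {
  set.seed(as.integer(seed))
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  Y <- cbind(pregrooming = as.numeric(y == "pregrooming"),
             other = as.numeric(y == "other"))

  n <- nrow(Z)
  vi <- sample(n, max(1L, round(valFraction * n)))
  if (length(unique(y[-vi])) < 2L) vi <- vi[-1L]  # keep both classes in train
  Ztr <- Z[-vi, , drop = FALSE]; Ytr <- Y[-vi, , drop = FALSE]
  Zva <- Z[vi, , drop = FALSE]; Yva <- Y[vi, , drop = FALSE]

  d <- ncol(Z); h1 <- hidden[1L]; h2 <- hidden[2L]
  ginit <- function(fi, fo) matrix(runif(fi * fo, -1, 1) * sqrt(6 / (fi + fo)),
                                   fi, fo)
  par <- list(W1 = ginit(d, h1), b1 = rep(0, h1),
              W2 = ginit(h1, h2), b2 = rep(0, h2),
              W3 = ginit(h2, 2L), b3 = rep(0, 2L))
  mAdam <- lapply(par, function(p) p * 0)
  vAdam <- lapply(par, function(p) p * 0)
  b1a <- 0.9; b2a <- 0.999; epsA <- 1e-8
  ce <- function(P, Y) -mean(rowSums(Y * log(pmax(P, 1e-12))))
  best <- par; bestVal <- Inf; wait <- 0L; ep <- 0L
  for (ep in seq_len(epochs)) {
    fw <- .mlpForward(par, Ztr)
    m <- nrow(Ztr)
    dO <- (fw$O - Ytr) / m
    g <- list()
    g$W3 <- t(fw$H2) %*% dO; g$b3 <- colSums(dO)
    dH2 <- (dO %*% t(par$W3)) * fw$H2 * (1 - fw$H2)
    g$W2 <- t(fw$H1) %*% dH2; g$b2 <- colSums(dH2)
    dH1 <- (dH2 %*% t(par$W2)) * fw$H1 * (1 - fw$H1)
    g$W1 <- t(Ztr) %*% dH1; g$b1 <- colSums(dH1)
    for (k in names(par)) {
      mAdam[[k]] <- b1a * mAdam[[k]] + (1 - b1a) * g[[k]]
      vAdam[[k]] <- b2a * vAdam[[k]] + (1 - b2a) * g[[k]]^2
      mh <- mAdam[[k]] / (1 - b1a^ep)
      vh <- vAdam[[k]] / (1 - b2a^ep)
      par[[k]] <- par[[k]] - lr * mh / (sqrt(vh) + epsA)
    }
    val <- ce(.mlpForward(par, Zva)$O, Yva)
    if (val < bestVal - 1e-6) {
      bestVal <- val; best <- par; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(par = best, valLoss = bestVal, mu = mu, sdv = sdv, epochs = ep)
}

#' Predict window class from features
#'
#' Applies the stored z-scoring exactly once, runs the network forward and
#' takes the class with the larger normalized output score. An exact tie
#' (score 0.5/0.5) resolves to \code{"other"}: the conservative choice for a
#' stimulation trigger, consistent with the strict majority voting rule.
#'
#' @param clf an \linkS4class{ElectrodeClassifier}.
#' @param features numeric vector of length M * P (a flattened
#'   \code{\link{featureMatrix}}), an M x P matrix, or a windows x features
#'   matrix for batch prediction.
#' @return list with \code{class} (character) and \code{score} (numeric
#'   matrix of class probabilities, columns \code{pregrooming}, \code{other}).
#' @export
predictElectrode <- function(clf, features) {
  stopifnot(is(clf, "ElectrodeClassifier"))
  d <- nrow(clf@W1)
  if (is.matrix(features) && !is.null(attr(features, "decision_time_s")))
    features <- flattenFeatures(features)
  if (!is.matrix(features)) features <- matrix(features, nrow = 1L)
  if (ncol(features) != d)
    stop("expected ", d, " features, got ", ncol(features))
  if (anyNA(features) || !all(is.finite(features)))
    stop("non-finite feature values")
  Z <- sweep(sweep(features, 2L, clf@featMean), 2L, clf@featSd, "/")
  O <- .mlpForward(list(W1 = clf@W1, b1 = clf@b1, W2 = clf@W2, b2 = clf@b2,
                        W3 = clf@W3, b3 = clf@b3), Z)$O
  colnames(O) <- c("pregrooming", "other")
  cls <- ifelse(O[, 1L] > 0.5, "pregrooming", "other")  # tie -> negative
  list(class = cls, score = O)
}

#' Electrode voting decision
#'
#' Combines per-electrode class outputs under the strict-majority policy:
#' the decision is triggered if and only if the fraction of electrodes
#' voting \code{"pregrooming"} strictly exceeds the policy threshold
#' (16 of 32 positives, exactly 50\%, does not trigger; 17 of 32 does).
#'
#' @param classes character vector of per-electrode outputs
#'   (\code{"pregrooming"} / \code{"other"}), at least one.
#' @param policy a \linkS4class{VotePolicy}; default strict majority.
#' @param t_s optional decision timestamp carried into the result.
#' @return list with \code{t_s}, \code{votes}, \code{positive_fraction} and
#'   \code{triggered}.
#' @export
vote <- function(classes, policy = votePolicy(), t_s = NA_real_) {
  stopifnot(is(policy, "VotePolicy"), length(classes) >= 1L)
  pos <- classes == "pregrooming"
  frac <- mean(pos)
  list(t_s = t_s, votes = pos, positive_fraction = frac,
       triggered = frac > policy@thresholdFraction)
}

#' Train one classifier per electrode
#'
#' Extracts per-electrode feature matrices for every labeled window of a
#' dataset split and trains one \linkS4class{ElectrodeClassifier} per
#' channel (electrodes are always processed individually; there is no pooled
#' model).
#'
#' @param windows data.frame from \code{\link{buildLabeledDataset}} (the
#'   \code{train} element).
#' @param recordings list of \linkS4class{Recording}, parallel to the
#'   session indices in \code{windows}.
#' @param fb a \linkS4class{FilterBank}.
#' @param cfg session configuration from \code{\link{sessionConfig}}.
#' @param seed integer RNG seed; each electrode trains with a derived seed.
#' @return a \linkS4class{ClassifierBank}.
#' @export
trainClassifierBank <- function(windows, recordings, fb = buildFilterbank(),
                                cfg = sessionConfig(), seed = 1L) {
  if (is(recordings, "Recording")) recordings <- list(recordings)
  feats <- extractWindowFeatures(windows, recordings, fb, cfg)
  ids <- names(feats)
  clfs <- vector("list", length(ids))
  names(clfs) <- ids
  for (k in seq_along(ids)) {
    clfs[[k]] <- trainElectrodeClassifier(
      feats[[k]], windows$label, seed = .childSeed(seed, k),
      hidden = cfg$classifier$hidden, epochs = cfg$classifier$epochs,
      lr = cfg$classifier$lr, valFraction = cfg$classifier$val_fraction,
      patience = cfg$classifier$patience,
      nStarts = cfg$classifier$n_starts %||% 3L, channelId = ids[k])
  }
  new("ClassifierBank", classifiers = clfs,
      featureConfig = cfg$features)
}

#' Per-electrode features for a set of labeled windows
#'
#' @param windows data.frame with columns \code{session} and \code{t_end_s}.
#' @param recordings list of \linkS4class{Recording}.
#' @param fb a \linkS4class{FilterBank}.
#' @param cfg session configuration.
#' @return named list (one element per channel) of windows x (M * P)
#'   feature matrices, rows parallel to \code{windows}.
#' @export
extractWindowFeatures <- function(windows, recordings,
                                  fb = buildFilterbank(),
                                  cfg = sessionConfig()) {
  if (is(recordings, "Recording")) recordings <- list(recordings)
  P <- cfg$features$P
  shiftS <- cfg$features$shift_s
  ids <- channelIds(recordings[[1L]])
  out <- lapply(ids, function(id)
    matrix(NA_real_, nrow = nrow(windows), ncol = fb@M * P))
  names(out) <- ids
  for (s in unique(windows$session)) {
    rec <- recordings[[s]]
    rows <- which(windows$session == s)
    ends <- windows$t_end_s[rows]
    allEnds <- as.vector(vapply(ends, function(e) e - (P:1 - 1L) * shiftS,
                                numeric(P)))
    x <- lfpSamples(rec)
    for (ch in seq_along(ids)) {
      co <- .windowCoefficients(x[ch, ], rateHz(rec), allEnds,
                                startTime(rec), fb, cfg$features$window_s,
                                logEnergies = cfg$features$log_energies)
      for (j in seq_along(rows)) {
        fm <- co[, ((j - 1L) * P + 1L):(j * P), drop = FALSE]
        out[[ch]][rows[j], ] <- as.numeric(t(fm))
      }
    }
  }
  out
}

#' Save or load a classifier bank
#'
#' The bundle is a single JSON file with all electrode networks, their
#' normalization statistics and the feature configuration.
#'
#' @param bank a \linkS4class{ClassifierBank}.
#' @param path file path (.json).
#' @return \code{readClassifierBank} returns the
#'   \linkS4class{ClassifierBank}.
#' @export
writeClassifierBank <- function(bank, path) {
  stopifnot(is(bank, "ClassifierBank"))
  mat <- function(m) list(nrow = nrow(m), data = as.numeric(m))
  ser <- list(featureConfig = bank@featureConfig,
              classifiers = lapply(bank@classifiers, function(c) list(
                W1 = mat(c@W1), b1 = c@b1, W2 = mat(c@W2), b2 = c@b2,
                W3 = mat(c@W3), b3 = c@b3, featMean = c@featMean,
                featSd = c@featSd, channelId = c@channelId, seed = c@seed,
                epochsRun = c@epochsRun)))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeClassifierBank
#' @export
readClassifierBank <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  unmat <- function(m)
    matrix(as.numeric(m$data), nrow = as.integer(m$nrow))
  clfs <- lapply(ser$classifiers, function(c) {
    new("ElectrodeClassifier", W1 = unmat(c$W1), b1 = as.numeric(c$b1),
        W2 = unmat(c$W2), b2 = as.numeric(c$b2), W3 = unmat(c$W3),
        b3 = as.numeric(c$b3), featMean = as.numeric(c$featMean),
        featSd = as.numeric(c$featSd), channelId = c$channelId,
        seed = as.integer(c$seed), epochsRun = as.integer(c$epochsRun))
  })
  new("ClassifierBank", classifiers = clfs,
      featureConfig = as.list(ser$featureConfig))
}
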
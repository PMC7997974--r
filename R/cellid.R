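# Candidate segmentation, engineered spectral/geometric features, the
# spectral-spatial normalized-cut subregion extractor, and the
# uncertainty-sampling active-learning classifier.

#' Segmentation parameters
#'
#' @param smooth_sigma Gaussian smoothing sigma (um).
#' @param background_radius scale of the local background estimate (um).
#' @param threshold global threshold applied after background subtraction.
#' @param seed_size minimum separation between splitting seed points (um).
#' @return list of class `lami_seg_params`.
#' @export
seg_params <- function(smooth_sigma = 2, background_radius = 20,
                       threshold = 2, seed_size = 6) {
  stopifnot(smooth_sigma > 0, background_radius > 0, seed_size > 0)
  structure(list(smooth_sigma = smooth_sigma,
                 background_radius = background_radius,
                 threshold = threshold, seed_size = seed_size),
            class = "lami_seg_params")
}

#' Segment cell candidates in a 3D volume
#'
#' Reference-channel pipeline: Gaussian smoothing, local background
#' subtraction (a wide-kernel smooth subtracted from the image, a
#' rolling-ball-style estimate), global thresholding, 6-connected
#' components, and a splitting step in which seed points (local maxima at
#' least `seed_size` apart) divide a component among its seeds by
#' proximity. Deterministic.
#'
#' @param volume 3D array (x, y, z), one channel.
#' @param params a `lami_seg_params`.
#' @param voxel_size voxel edge lengths (um), length 1 or 3.
#' @return list of candidate regions, each `list(id, voxels)` with `voxels`
#'   an n x 3 integer matrix of voxel coordinates.
#' @export
segment_candidates <- function(volume, params = seg_params(),
                               voxel_size = 1) {
  if (all(volume == 0)) return(list())
  vs <- rep(voxel_size, length.out = 3)
  sm <- gauss_smooth(volume, params$smooth_sigma / vs)
  bg <- gauss_smooth(volume, params$background_radius / vs)
  sub <- pmax(sm - bg, 0)
  mask <- sub > params$threshold
  if (!any(mask)) return(list())
  lab <- label_components3d(mask)
  out <- list()
  id <- 0L
  for (l in seq_len(max(lab))) {
    vox_i <- which(lab == l)
    vox <- index_to_coord3d(vox_i, dim(volume))
    seeds <- find_seeds(sub, vox, vs, params$seed_size)
    if (nrow(seeds) <= 1L) {
      id <- id + 1L
      out[[id]] <- list(id = id, voxels = vox, label = "unlabeled")
    } else {
      # split voxels by nearest seed (um metric)
      um <- sweep(vox, 2, vs, `*`)
      sm_um <- sweep(seeds, 2, vs, `*`)
      d2 <- outer(rowSums(um^2), rep(1, nrow(sm_um))) -
        2 * um %*% t(sm_um) +
        outer(rep(1, nrow(um)), rowSums(sm_um^2))
      assign <- max.col(-d2)
      for (s in seq_len(nrow(seeds))) {
        id <- id + 1L
        out[[id]] <- list(id = id, voxels = vox[assign == s, , drop = FALSE],
                          label = "unlabeled")
      }
    }
  }
  out
}

# local maxima of `img` among the voxels `vox` of one component, kept
# greedily with minimum separation `seed_size` (um)
find_seeds <- function(img, vox, vs, seed_size) {
  d <- dim(img)
  vals <- img[vox]
  is_max <- rep(TRUE, nrow(vox))
  for (k in 1:3) for (s in c(-1L, 1L)) {
    nb <- vox
    nb[, k] <- clamp(nb[, k] + s, 1L, d[k])
    is_max <- is_max & vals >= img[nb]
  }
  cand <- vox[is_max, , drop = FALSE]
  cv <- vals[is_max]
  ord <- order(cv, decreasing = TRUE)
  kept <- matrix(numeric(0), 0, 3)
  for (i in ord) {
    p <- cand[i, ] * vs
    if (nrow(kept) == 0 ||
        all(rowSums(sweep(sweep(kept, 2, vs, `*`), 2, p)^2) >= seed_size^2))
      kept <- rbind(kept, cand[i, ])
  }
  kept
}

#' Engineered spectral/geometric features of a candidate region
#'
#' In fixed order: the background-subtracted channel-mean vector normalized
#' to unit length (the "spectrum"), its pre-normalization magnitude, a
#' zero-spectrum flag, all pairwise distances between the
#' intensity-weighted centers of mass (COM) of the channels, the distance
#' from each channel COM to the unweighted centroid, the upper triangle of
#' the channel-channel voxel correlation matrix, then base statistics
#' (per-channel mean, sd, min, max; voxel count; bounding-box extents).
#' COM spread across channels flags composite regions enclosing two
#' spectrally distinct cells.
#'
#' @param region candidate region (`list(voxels = ...)`).
#' @param volume 4D array (x, y, z, channel).
#' @param backgrounds per-channel background pixel values; default: median
#'   over the volume of each channel.
#' @param voxel_size voxel edge lengths (um), length 1 or 3.
#' @return named numeric feature vector.
#' @export
engineer_features <- function(region, volume, backgrounds = NULL,
                              voxel_size = 1) {
  vox <- region$voxels
  if (nrow(vox) == 0) stop("empty candidate region")
  vs <- rep(voxel_size, length.out = 3)
  nc <- dim(volume)[4]
  if (is.null(backgrounds))
    backgrounds <- vapply(seq_len(nc), function(c)
      stats::median(volume[, , , c]), 0)
  inten <- vapply(seq_len(nc), function(c) {
    ch <- volume[, , , c]
    ch[vox]
  }, numeric(nrow(vox)))
  inten <- matrix(inten, nrow = nrow(vox))
  mu <- colMeans(inten)
  v <- mu - backgrounds
  mag <- sqrt(sum(v^2))
  if (mag > 0) {
    spec <- v / mag
    flag <- 0
  } else {
    spec <- rep(0, nc)
    flag <- 1
  }
  um <- sweep(vox, 2, vs, `*`)
  centroid <- colMeans(um)
  coms <- t(vapply(seq_len(nc), function(c) {
    w <- pmax(inten[, c] - backgrounds[c], 0)
    if (sum(w) == 0) centroid else colSums(um * w) / sum(w)
  }, numeric(3)))
  ut <- which(upper.tri(diag(nc)), arr.ind = TRUE)
  com_pair <- sqrt(rowSums((coms[ut[, 1], , drop = FALSE] -
                              coms[ut[, 2], , drop = FALSE])^2))
  com_centroid <- sqrt(rowSums(sweep(coms, 2, centroid)^2))
  cm <- suppressWarnings(stats::cor(inten))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 1
  corr <- cm[upper.tri(cm)]
  base <- c(mu, apply(inten, 2, stats::sd), apply(inten, 2, min),
            apply(inten, 2, max))
  base[!is.finite(base)] <- 0
  bbox <- apply(um, 2, function(x) diff(range(x)))
  out <- c(spec, mag, flag, com_pair, com_centroid, corr, base,
           nrow(vox), bbox)
  names(out) <- c(paste0("spec_", seq_len(nc)), "magnitude", "zero_flag",
                  paste0("com_d_", ut[, 1], "_", ut[, 2]),
                  paste0("com_centroid_", seq_len(nc)),
                  paste0("cor_", ut[, 1], "_", ut[, 2]),
                  paste0("mean_", seq_len(nc)), paste0("sd_", seq_len(nc)),
                  paste0("min_", seq_len(nc)), paste0("max_", seq_len(nc)),
                  "voxel_count", paste0("bbox_", c("x", "y", "z")))
  out
}

#' Normalized-cut configuration
#'
#' @param alpha spatial weight (1/um^2).
#' @param beta spectral weight (dimensionless).
#' @param clusters number of clusters (>= 2).
#' @return list of class `lami_nc_config`.
#' @export
nc_config <- function(alpha = 0.01, beta = 5, clusters = 2) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (clusters < 2) stop("need at least 2 clusters")
  structure(list(alpha = alpha, beta = beta, clusters = clusters),
            class = "lami_nc_config")
}

#' Spectral-spatial normalized-cut region of interest
#'
#' Builds a voxel adjacency `w_ij = exp(-d_ij)` from combined spatial and
#' spectral distances, partitions the candidate's voxels by normalized-cut
#' spectral clustering, and returns the cluster whose mean unit spectrum is
#' most similar (largest dot product) to the reference spectrum. The
#' default spectral term is `beta * (1 - s_i . s_j)`, so similar spectra
#' give small distance and large adjacency; `literal_formula = TRUE`
#' instead uses `beta * s_i . s_j` of the literal distance formula.
#' Ties between equally similar clusters go to the larger one.
#'
#' @param region candidate region (`list(voxels = ...)`).
#' @param volume 4D array (x, y, z, channel).
#' @param reference unit reference spectrum (length = channels).
#' @param config a `lami_nc_config`.
#' @param voxel_size voxel edge lengths (um).
#' @param literal_formula use the literal similarity-as-distance form.
#' @param seed k-means seed.
#' @return list with `voxels` (subregion coordinates), `members` (logical
#'   over the region's voxels) and `cluster` assignments.
#' @export
nc_roi <- function(region, volume, reference, config = nc_config(),
                   voxel_size = 1, literal_formula = FALSE, seed = 1) {
  vox <- region$voxels
  n <- nrow(vox)
  if (n < config$clusters) stop("region has fewer voxels than clusters")
  vs <- rep(voxel_size, length.out = 3)
  nc <- dim(volume)[4]
  inten <- matrix(vapply(seq_len(nc), function(c) volume[, , , c][vox],
                         numeric(n)), nrow = n)
  nrm <- sqrt(rowSums(inten^2))
  s <- inten / pmax(nrm, 1e-12)
  s[nrm == 0, ] <- 0
  um <- sweep(vox, 2, vs, `*`)
  sp2 <- as.matrix(stats::dist(um))^2
  dot <- s %*% t(s)
  d <- if (literal_formula) config$alpha * sp2 + config$beta * dot
  else config$alpha * sp2 + config$beta * (1 - dot)
  w <- exp(-d)
  cl <- spectral_cluster(w, config$clusters, seed = seed)
  ref <- reference / sqrt(sum(reference^2))
  sim <- vapply(seq_len(config$clusters), function(k) {
    ms <- colMeans(s[cl == k, , drop = FALSE])
    ms <- ms / max(sqrt(sum(ms^2)), 1e-12)
    sum(ms * ref)
  }, 0)
  sizes <- tabulate(cl, config$clusters)
  best <- which(sim >= max(sim) - 1e-9)
  pick <- best[which.max(sizes[best])]
  members <- cl == pick
  list(voxels = vox[members, , drop = FALSE], members = members,
       cluster = cl)
}

# normalized-cut spectral clustering (symmetric normalized affinity,
# leading eigenvectors, row normalization, k-means)
spectral_cluster <- function(w, k, seed = 1) {
  n <- nrow(w)
  deg <- rowSums(w)
  isolated <- deg <= .Machine$double.eps
  dd <- 1 / sqrt(pmax(deg, .Machine$double.eps))
  L <- w * (dd %o% dd)
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  U <- U / pmax(sqrt(rowSums(U^2)), 1e-12)
  set.seed(seed)
  km <- stats::kmeans(U, centers = k, nstart = 10)
  cl <- km$cluster
  # an isolated voxel forms its own cluster side
  if (any(isolated)) cl[isolated] <- cl[isolated]
  cl
}

#' Train the candidate-classifier ensemble
#'
#' Small fully connected networks (12 hidden units) trained on labeled
#' candidate features; member predictions are averaged. Three members are
#' used during active learning, more (e.g. 100) for final predictions.
#'
#' @param X feature matrix (rows = candidates).
#' @param y labels (0/1); both classes must be present.
#' @param members ensemble size.
#' @param hidden hidden units per member.
#' @param seed base RNG seed; member `i` uses `seed + i`.
#' @param epochs training epochs per member.
#' @return object of class `lami_ensemble`.
#' @export
train_classifier <- function(X, y, members = 3, hidden = 12, seed = 1,
                             epochs = 150) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("need at least one label from each class")
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  loss_grad <- function(pred, target) {
    p <- 1 / (1 + exp(-pred))
    eps <- 1e-9
    list(loss = -mean(target * log(p + eps) + (1 - target) * log(1 - p + eps)),
         dpred = p - target)
  }
  nets <- lapply(seq_len(members), function(i)
    nn_train(Xs, y, loss_grad, hidden = hidden, dropout = 0,
             batch_size = nrow(Xs), lr = 0.05, max_epochs = epochs,
             patience = epochs, val_frac = 0, seed = seed + i)$par)
  structure(list(nets = nets, mu = mu, sd = sds), class = "lami_ensemble")
}

#' Ensemble scores for candidates
#'
#' Mean of the member networks' sigmoid outputs, in [0, 1] (0 and 1 are
#' complete certainty of the two classes).
#'
#' @param ensemble a `lami_ensemble`.
#' @param X feature matrix.
#' @return numeric scores in [0, 1].
#' @export
predict_ensemble <- function(ensemble, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, ensemble$mu), 2, ensemble$sd, "/")
  sc <- vapply(ensemble$nets, function(p) 1 / (1 + exp(-nn_predict(p, Xs))),
               numeric(nrow(Xs)))
  rowMeans(matrix(sc, nrow = nrow(Xs)))
}

#' Uncertainty-sampling query
#'
#' The unlabeled example whose ensemble score is closest to 0.5 (ties
#' broken by lowest index) — the next candidate sent for labeling.
#'
#' @param ensemble a `lami_ensemble`.
#' @param X unlabeled pool feature matrix (non-empty).
#' @return integer index into the pool.
#' @export
uncertainty_select <- function(ensemble, X) {
  if (NROW(X) == 0) stop("empty unlabeled pool")
  which.min(abs(predict_ensemble(ensemble, X) - 0.5))
}

balanced_accuracy <- function(truth, pred) {
  pos <- truth == 1; neg <- !pos
  se <- if (any(pos)) mean(pred[pos] == 1) else NA_real_
  sp <- if (any(neg)) mean(pred[neg] == 0) else NA_real_
  mean(c(se, sp), na.rm = TRUE)
}

#' Simulated labeling experiment: uncertainty vs random sampling
#'
#' Replays active learning against a fully labeled ground-truth pool: one
#' positive and one negative candidate are drawn at random as the initial
#' labels, then the chosen strategy repeatedly selects the next example,
#' receives its ground-truth label, and the ensemble is retrained. After
#' each evaluation step the accuracy (raw and balanced) on the remaining
#' unlabeled examples is recorded.
#'
#' @param X pool feature matrix.
#' @param y ground-truth labels (0/1).
#' @param strategy `"uncertainty"` or `"random"`.
#' @param budget maximum number of labels to spend.
#' @param members ensemble members during learning.
#' @param eval_every evaluate (and, for `"random"`, retrain) every this
#'   many labels.
#' @param seed RNG seed (shared seeds give comparable curves).
#' @return data.frame learning curve: `labels`, `accuracy`,
#'   `balanced_accuracy`.
#' @export
simulate_labeling_experiment <- function(X, y, strategy = c("uncertainty",
                                                            "random"),
                                         budget = 100, members = 3,
                                         eval_every = 1, seed = 1) {
  strategy <- match.arg(strategy)
  X <- as.matrix(X)
  y <- as.numeric(y)
  set.seed(seed)
  labeled <- c(sample(which(y == 1), 1), sample(which(y == 0), 1))
  curve <- NULL
  ens <- NULL
  repeat {
    pool <- setdiff(seq_along(y), labeled)
    do_eval <- length(labeled) %% eval_every == 0 || length(labeled) == 2
    need_train <- strategy == "uncertainty" || do_eval || is.null(ens)
    if (need_train)
      ens <- train_classifier(X[labeled, , drop = FALSE], y[labeled],
                              members = members, seed = seed + length(labeled))
    if (length(pool) == 0) break
    if (do_eval) {
      sc <- predict_ensemble(ens, X[pool, , drop = FALSE])
      pred <- as.integer(sc > 0.5)
      curve <- rbind(curve, data.frame(
        labels = length(labeled),
        accuracy = mean(pred == y[pool]),
        balanced_accuracy = balanced_accuracy(y[pool], pred)))
    }
    if (length(labeled) >= budget) break
    nxt <- if (strategy == "uncertainty")
      pool[uncertainty_select(ens, X[pool, , drop = FALSE])]
    else sample(pool, 1)
    labeled <- c(labeled, nxt)
  }
  curve
}

#' Synthetic imbalanced candidate pool
#'
#' Two Gaussian clusters in feature space with configurable positive
#' prevalence (default 0.5%, mirroring rare labeled T cells among tens of
#' thousands of candidates) and partial overlap.
#'
#' @param n pool size.
#' @param prevalence positive fraction.
#' @param dim feature dimensionality.
#' @param separation distance between class means (in noise SDs).
#' @param seed RNG seed.
#' @return list with `X` and `y`.
#' @export
synthetic_pool <- function(n = 4000, prevalence = 0.005, dim = 2,
                           separation = 3.5, seed = 1) {
  set.seed(seed)
  n_pos <- max(2L, round(n * prevalence))
  n_neg <- n - n_pos
  mu_pos <- c(separation, rep(0, dim - 1))
  X <- rbind(
    matrix(stats::rnorm(n_pos * dim), n_pos, dim) +
      matrix(mu_pos, n_pos, dim, byrow = TRUE),
    matrix(stats::rnorm(n_neg * dim), n_neg, dim))
  y <- c(rep(1, n_pos), rep(0, n_neg))
  ord <- sample.int(n)
  list(X = X[ord, , drop = FALSE], y = y[ord])
}
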
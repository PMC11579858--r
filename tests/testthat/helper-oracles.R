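# Independent brute-force oracles used across the suite. These loop over
# cells/genes/pairs with base R only, so they share no code path with the
# vectorized implementations they check.

# Feature-selection F-score, looped gene by gene and class by class.
# Binary: squared deviations of class means from the global mean over the
# summed within-class sample variances; multiclass: mean of one-vs-rest.
oracle_fscore <- function(x, y, eps = 1e-12) {
  classes <- sort(unique(y))
  vapply(seq_len(ncol(x)), function(j) {
    vals <- x[, j]
    fs <- vapply(classes, function(cl) {
      pos <- vals[y == cl]
      neg <- vals[y != cl]
      num <- (mean(pos) - mean(vals))^2 + (mean(neg) - mean(vals))^2
      if (num == 0) return(0)
      num / (stats::var(pos) + stats::var(neg) + eps)
    }, numeric(1))
    if (length(classes) == 2) fs[[1]] else mean(fs)
  }, numeric(1))
}

# AUC as the probability a random positive outranks a random negative,
# ties counting one half, over all positive x negative pairs.
oracle_auc <- function(y_binary, scores) {
  pos <- scores[y_binary]
  neg <- scores[!y_binary]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# PCA importance via an explicit eigendecomposition of the covariance of
# the standardized matrix (constant genes pinned to zero).
oracle_pca_importance <- function(x, k) {
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0
  xs <- scale(x, center = TRUE, scale = ifelse(const, 1, sds))
  xs[, const] <- 0
  ev <- eigen(stats::cov(xs), symmetric = TRUE)
  evr <- ev$values / sum(ev$values)
  imp <- as.numeric(abs(ev$vectors[, seq_len(k), drop = FALSE]) %*%
                      evr[seq_len(k)])
  imp[const] <- 0
  imp
}

# Plain looped k-nearest-neighbour prediction (Euclidean, ties by
# training order), for checking grid-search choices independently.
oracle_knn_predict <- function(X_train, y_train, X_test, k) {
  k <- min(k, nrow(X_train))
  classes <- sort(unique(y_train))
  apply(X_test, 1, function(v) {
    d <- sqrt(colSums((t(X_train) - v)^2))
    nn <- y_train[order(d)[seq_len(k)]]
    votes <- table(factor(nn, levels = classes))
    classes[which.max(votes)]
  })
}

# Random labelled toy matrix with guaranteed class sizes.
random_toy <- function(n_per_class, n_genes, n_classes, seed,
                       shift_gene = NULL, shift = 0) {
  set.seed(seed)
  y <- rep(paste0("c", seq_len(n_classes)), each = n_per_class)
  x <- matrix(round(abs(rnorm(length(y) * n_genes, 5, 2)), 3),
              nrow = length(y))
  if (!is.null(shift_gene))
    for (k in seq_along(shift_gene)) {       # round-robin over classes
      cl <- paste0("c", (k - 1) %% n_classes + 1)
      x[y == cl, shift_gene[k]] <- x[y == cl, shift_gene[k]] + shift
    }
  colnames(x) <- paste0("g", seq_len(n_genes))
  sc_matrix(x, labels = y)
}

# Five cells with prescribed (detected genes, total UMIs, mito%) profiles;
# fractional counts let every combination be represented exactly.
qc_toy <- function() {
  build_cell <- function(n_genes, umis, mito_pct) {
    v <- numeric(400)
    v[1] <- umis * mito_pct / 100            # the single MT- gene
    v[2:n_genes] <- (umis - v[1]) / (n_genes - 1)
    v
  }
  x <- rbind(build_cell(300, 500, 5), build_cell(150, 500, 5),
             build_cell(300, 100, 5), build_cell(300, 500, 25),
             build_cell(201, 251, 19.9))
  sc_matrix(x, gene_ids = c("MT-ND1", paste0("g", 1:399)),
            cell_ids = paste0("cell", 1:5))
}

# Toy where a handful of indicator genes separate the classes perfectly
# and the rest are pure noise.
perfect_marker_toy <- function(n_classes = 5, n_per_class = 12,
                               n_noise = 595, seed = 42) {
  set.seed(seed)
  y <- rep(paste0("c", seq_len(n_classes)), each = n_per_class)
  markers <- sapply(seq_len(n_classes), function(k)
    ifelse(y == paste0("c", k), 10, 0))
  noise <- matrix(abs(rnorm(length(y) * n_noise, 5, 1)), nrow = length(y))
  x <- cbind(markers, noise)
  colnames(x) <- c(paste0("marker", seq_len(n_classes)),
                   paste0("noise", seq_len(n_noise)))
  sc_matrix(x, labels = y)
}
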
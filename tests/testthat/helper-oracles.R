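# Independent oracles used across tests. These deliberately use naive
# double loops / O(n^2) scans so they share no code with the implementation.

# Haralick features by explicit double summation over matrix entries.
brute_glcm_features <- function(p) {
  n <- nrow(p)
  mu_i <- 0; mu_j <- 0
  for (i in 1:n) for (j in 1:n) {
    mu_i <- mu_i + (i - 1) * p[i, j]
    mu_j <- mu_j + (j - 1) * p[i, j]
  }
  var_i <- 0; var_j <- 0
  for (i in 1:n) for (j in 1:n) {
    var_i <- var_i + (i - 1 - mu_i)^2 * p[i, j]
    var_j <- var_j + (j - 1 - mu_j)^2 * p[i, j]
  }
  energy <- 0; contrast <- 0; prom <- 0; corr <- 0
  for (i in 1:n) for (j in 1:n) {
    energy <- energy + p[i, j]^2
    contrast <- contrast + ((i - 1) - (j - 1))^2 * p[i, j]
    prom <- prom + ((i - 1) + (j - 1) - mu_i - mu_j)^4 * p[i, j]
    corr <- corr + (i - 1 - mu_i) * (j - 1 - mu_j) * p[i, j]
  }
  s <- sqrt(var_i * var_j)
  corr <- if (s == 0) 1 else corr / s
  c(energy = energy, contrast = contrast, prominence = prom,
    correlation = corr)
}

# O(n^2) neighbor counting: for each gamma-H2AX+ center, per-class counts
# of other positives and count of CD8+ cells within radius (lateral px).
brute_neighbor_counts <- function(cells, class_of, radius, voxel_size) {
  s <- voxel_size / voxel_size[2]
  pos <- which(cells$gh2ax_pos)
  cd8 <- which(cells$cd8_pos)
  k <- max(class_of, na.rm = TRUE) + 1L
  res <- list()
  for (a in pos) {
    cnt <- integer(k); nc <- 0L
    for (b in pos) {
      if (a == b) next
      d <- sqrt(((cells$centroid_z[a] - cells$centroid_z[b]) * s[1])^2 +
                ((cells$centroid_y[a] - cells$centroid_y[b]) * s[2])^2 +
                ((cells$centroid_x[a] - cells$centroid_x[b]) * s[3])^2)
      if (d > 0 && d <= radius)
        cnt[class_of[b] + 1L] <- cnt[class_of[b] + 1L] + 1L
    }
    for (b in cd8) {
      if (a == b) next
      d <- sqrt(((cells$centroid_z[a] - cells$centroid_z[b]) * s[1])^2 +
                ((cells$centroid_y[a] - cells$centroid_y[b]) * s[2])^2 +
                ((cells$centroid_x[a] - cells$centroid_x[b]) * s[3])^2)
      if (d > 0 && d <= radius) nc <- nc + 1L
    }
    res[[length(res) + 1L]] <- list(cell_id = cells$cell_id[a],
                                    counts = cnt, cd8 = nc)
  }
  res
}

# Per-instance overlap fractions by a plain voxel loop (no dilation).
brute_overlap <- function(labels, mask) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  sapply(ids, function(i) sum(mask[labels == i]) / sum(labels == i))
}

# Adjusted Rand index from a contingency table of two labelings.
ari_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  sab <- sum(choose(tab, 2))
  e <- sa * sb / choose(n, 2)
  (sab - e) / ((sa + sb) / 2 - e)
}

# Small two-class patch bank (the package's default planted phenotypes)
# shared by texture-separability tests.
two_class_bank <- function(n_per_class = 50, seed = 11) {
  generate_patch_bank(default_texture_classes(), n_per_class, seed = seed)
}
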
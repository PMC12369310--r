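#' Cluster muscle synergies across animals
#'
#' K-means clustering of L2-normalized synergy vectors (Euclidean distance,
#' 50 seeded restarts per k), scanned over k = 2..10 (capped at one less
#' than the number of synergies). Clustering quality at each k is the mean
#' silhouette value; the selected k is the first local maximum of the mean
#' silhouette in ascending k (edges compared one-sided).
#'
#' @param W Matrix `[n_muscles x n_synergies]` of synergy columns, pooled
#'   over animals (at least 3 columns).
#' @param k_range Inclusive k limits (default `c(2, 10)`).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Restarts per k.
#' @return An object of class `"cluster_result"`: list with `k_selected`,
#'   `labels` (per synergy), `silhouette_by_k` (tibble `k`, `silhouette`)
#'   and `centers` of the selected clustering.
#' @export
cluster_synergies <- function(W, k_range = c(2, 10), seed = 1L, nstart = 50) {
  W <- as.matrix(W)
  n_syn <- ncol(W)
  if (n_syn < 3) stop("need at least 3 synergies to cluster")
  X <- t(sweep(W, 2, sqrt(colSums(W^2)), "/"))  # synergies x muscles
  n_distinct <- nrow(unique(X))
  k_hi <- min(k_range[2], n_syn - 1, n_distinct)
  if (k_hi < 2) stop("too few distinct synergies to cluster")
  ks <- seq(max(2, k_range[1]), k_hi)
  d <- stats::dist(X)

  fits <- with_stage_seed(seed, "kmeans", {
    purrr::map(ks, function(k) {
      km <- kmeans(X, centers = k, nstart = nstart, iter.max = 100)
      sil <- cluster::silhouette(km$cluster, d)
      list(k = k, fit = km, sil = mean(sil[, "sil_width"]))
    })
  })
  sil_by_k <- tibble::tibble(k = ks, silhouette = purrr::map_dbl(fits, "sil"))

  s <- sil_by_k$silhouette
  is_local_max <- purrr::map_lgl(seq_along(s), function(i) {
    left_ok <- i == 1 || s[i] >= s[i - 1]
    right_ok <- i == length(s) || s[i] >= s[i + 1]
    left_ok && right_ok
  })
  sel <- which(is_local_max)[1]
  chosen <- fits[[sel]]

  structure(
    list(k_selected = ks[sel],
         labels = as.integer(chosen$fit$cluster),
         silhouette_by_k = sil_by_k,
         silhouette_selected = chosen$sil,
         centers = chosen$fit$centers),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d (mean silhouette %.3f) over %d synergies\n",
              x$k_selected, x$silhouette_selected, length(x$labels)))
  print(x$silhouette_by_k, n = Inf)
  invisible(x)
}

#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble::tibble(synergy = seq_along(x$labels), cluster = x$labels)
}

#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(k_selected = x$k_selected,
                 silhouette = x$silhouette_selected,
                 n_synergies = length(x$labels))
}
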
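#' Self-organizing map clustering of temporal ratio profiles
#'
#' Trains a small rectangular SOM on per-gene log2-ratio profiles (one
#' dimension per day) and assigns every gene to its best-matching (Euclidean)
#' node. Training is the classical online algorithm: codebook vectors are
#' initialized uniformly over the per-day data range, and over `epochs`
#' passes through the genes (random order per epoch) each sample pulls its
#' best-matching unit and that unit's lattice neighbours toward itself under
#' a Gaussian neighbourhood; learning rate and neighbourhood radius decay
#' linearly from their first to their second value. A final zero-radius
#' batch phase ("polish") then iterates assign-to-nearest / recompute-means
#' to a fixed point, so each codebook ends exactly at its members' centroid
#' (empty nodes keep their trained codebook and are reported, not dropped).
#'
#' Cluster labels are canonicalized by sorting nodes on their last-day
#' codebook value, descending, so cluster 1 is reproducibly the strongest
#' up-regulated profile.
#'
#' @param profiles numeric matrix, genes x days (e.g. from
#'   [ratio_profiles()]); must have at least one row.
#' @param grid `c(rows, cols)` lattice shape; default `c(3, 2)`.
#' @param epochs online training epochs.
#' @param alpha learning-rate schedule `c(start, end)`.
#' @param radius neighbourhood-radius schedule `c(start, end)` in lattice
#'   units.
#' @param polish run the zero-radius batch refinement (default `TRUE`).
#' @param seed RNG seed; identical seed reproduces identical assignments.
#' @return Object of class `som_map`: list with `codebook` (clusters x days,
#'   canonical order), `assignment` (named integer vector), `grid`, `sizes`,
#'   and the training parameters.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 120,
#'   archetypes = default_archetypes(c(20, 20, 20, 20, 20, 20)),
#'   noise_sd = 0.1, seed = 3))
#' prof <- ratio_profiles(sim$expr, sim$truth$planted_genes)
#' fit <- som_fit(prof, seed = 3)
#' fit
#' @export
som_fit <- function(profiles, grid = c(3, 2), epochs = 500,
                    alpha = c(0.5, 0.01), radius = c(1, 0.5),
                    polish = TRUE, seed = NULL) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 1L) stop("need at least one profile", call. = FALSE)
  if (any(!is.finite(profiles)))
    stop("profiles contain non-finite values", call. = FALSE)
  if (length(grid) != 2L || any(grid < 1))
    stop("grid must be c(rows, cols) with positive entries", call. = FALSE)
  if (epochs < 1 || any(alpha <= 0) || any(radius <= 0))
    stop("invalid training schedule", call. = FALSE)
  G <- nrow(profiles); D <- ncol(profiles)
  nd <- prod(grid)
  pos <- as.matrix(expand.grid(row = seq_len(grid[1]), col = seq_len(grid[2])))
  gridd2 <- as.matrix(stats::dist(pos))^2

  with_seed(seed, {
    rng <- apply(profiles, 2, range)
    if (G == 1L) rng <- rbind(profiles[1, ] - 1, profiles[1, ] + 1)
    W <- sapply(seq_len(D), function(j) stats::runif(nd, rng[1, j], rng[2, j]))
    W <- matrix(W, nd, D)

    for (e in seq_len(epochs)) {
      frac <- if (epochs > 1) (e - 1) / (epochs - 1) else 0
      lr <- alpha[1] + (alpha[2] - alpha[1]) * frac
      rad <- radius[1] + (radius[2] - radius[1]) * frac
      H <- exp(-gridd2 / (2 * rad^2))
      for (i in sample.int(G)) {
        x <- profiles[i, ]
        xm <- matrix(x, nd, D, byrow = TRUE)
        bmu <- which.min(rowSums((W - xm)^2))
        W <- W + lr * H[, bmu] * (xm - W)
      }
    }

    assign_nearest <- function(W) {
      d2 <- outer(rowSums(profiles^2), rep(1, nd)) +
        outer(rep(1, G), rowSums(W^2)) - 2 * profiles %*% t(W)
      max.col(-d2, ties.method = "first")
    }
    asg <- assign_nearest(W)
    if (polish) {
      for (it in seq_len(200L)) {
        for (j in seq_len(nd)) {
          mem <- asg == j
          if (any(mem)) W[j, ] <- colMeans(profiles[mem, , drop = FALSE])
        }
        repaired <- FALSE
        if (G >= nd) {
          # reseed one empty node per pass on the profile farthest from its
          # centroid (standard k-means empty-cluster repair); nodes stay
          # empty only when there are fewer profiles than nodes
          empty <- which(tabulate(asg, nd) == 0L)
          if (length(empty)) {
            d_own <- rowSums((profiles - W[asg, , drop = FALSE])^2)
            W[empty[1L], ] <- profiles[which.max(d_own), ]
            repaired <- TRUE
          }
        }
        new <- assign_nearest(W)
        if (!repaired && identical(new, asg)) break
        asg <- new
      }
    }

    # canonical labels: strongest last-day up-profile first
    ord <- order(-W[, D], pos[, 1], pos[, 2])
    relabel <- match(seq_len(nd), ord)
    W <- W[ord, , drop = FALSE]
    pos <- pos[ord, , drop = FALSE]
    asg <- relabel[asg]
    names(asg) <- rownames(profiles)
    rownames(W) <- paste0("cluster", seq_len(nd))
    colnames(W) <- colnames(profiles)
    sizes <- tabulate(asg, nbins = nd)
    structure(list(codebook = W, assignment = asg, grid = grid,
                   node_pos = pos, sizes = sizes, epochs = epochs,
                   alpha = alpha, radius = radius, polish = polish,
                   seed = seed), class = "som_map")
  })
}

#' @export
print.som_map <- function(x, ...) {
  cat("SOM map ", x$grid[1], "x", x$grid[2], " on ", length(x$assignment),
      " profiles (", sum(x$sizes > 0), " non-empty clusters)\n", sep = "")
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("codebook:\n")
  print(round(x$codebook, 3))
  invisible(x)
}

#' @export
predict.som_map <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  W <- object$codebook
  d2 <- outer(rowSums(newdata^2), rep(1, nrow(W))) +
    outer(rep(1, nrow(newdata)), rowSums(W^2)) - 2 * newdata %*% t(W)
  out <- max.col(-d2, ties.method = "first")
  names(out) <- rownames(newdata)
  out
}

#' @export
plot.som_map <- function(x, ...) {
  graphics::matplot(t(x$codebook), type = "b", pch = 16, lty = 1,
                    xlab = "day index", ylab = "codebook log2 ratio",
                    main = "SOM codebook profiles", ...)
  graphics::legend("topleft", legend = rownames(x$codebook),
                   col = seq_len(nrow(x$codebook)), lty = 1, cex = 0.7)
  invisible(x)
}
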
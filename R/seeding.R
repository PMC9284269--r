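#' Dynamic radius parameter T
#'
#' Evaluates the fitted linear model for the dynamic radius parameter,
#' \deqn{T = -0.423 + 0.328 K - 1.211\,\bar d + 0.662\,\max(d) + 1.631\,\min(d),}
#' where \code{K} is a (rough) hint at the number of clusters, \eqn{\bar d}
#' the mean dissimilarity over all \code{n^2} pairs, \code{max(d)} the
#' largest dissimilarity and \code{min(d)} the smallest off-diagonal
#' (non-self) dissimilarity. The coefficients are taken as given
#' constants of the method. Because the K coefficient is small (0.328),
#' an approximate hint suffices; no iteration on K is performed.
#'
#' @param k_hint Positive integer, approximate number of clusters.
#' @param mean_d,max_d,min_d_offdiag Dissimilarity summary statistics,
#'   e.g. from \code{\link{diss_summary}}.
#' @return The scalar T.
#' @examples
#' dynamic_T(2, mean_d = 0.45, max_d = 1, min_d_offdiag = 0.2)  # 0.67625
#' @export
dynamic_T <- function(k_hint, mean_d, max_d, min_d_offdiag) {
  stopifnot(is.numeric(k_hint), length(k_hint) == 1L, k_hint >= 1,
            is.finite(mean_d), is.finite(max_d), is.finite(min_d_offdiag))
  T <- -0.423 + 0.328 * k_hint - 1.211 * mean_d +
    0.662 * max_d + 1.631 * min_d_offdiag
  if (T <= 0)
    stop(sprintf(paste0(
      "dynamic radius parameter T = %.4g is not positive for these ",
      "dissimilarity statistics; supply a manual positive T instead"), T))
  T
}

#' Dynamic radius
#'
#' The neighbourhood radius used for density counting and centre-removal,
#' \code{r = mean_d / T}: the mean pairwise dissimilarity scaled by the
#' dynamic parameter so the radius adapts to how scattered the data are.
#'
#' @param mean_d Mean dissimilarity over all \code{n^2} pairs.
#' @param T Positive dynamic radius parameter, see \code{\link{dynamic_T}}.
#' @return The radius r.
#' @examples
#' dynamic_radius(0.45, 0.67625)
#' @export
dynamic_radius <- function(mean_d, T) {
  stopifnot(is.finite(mean_d), length(T) == 1L)
  if (!is.finite(T) || T <= 0) stop("'T' must be a positive number")
  mean_d / T
}

#' Dissimilarity density
#'
#' For each point of \code{active}, the number of active points (itself
#' included, since \code{d_ii = 0 <= r}) whose dissimilarity to it is at
#' most \code{r}.
#'
#' @param D Dissimilarity matrix (a \code{"d3k_dissim"} or plain matrix).
#' @param r Positive radius.
#' @param active Integer vector of active sample indices (default: all).
#' @return Integer vector of densities, aligned with \code{active}.
#' @examples
#' D <- dissimilarity_matrix(cbind(c(0, 1, 4, 5)))
#' dissimilarity_density(D, r = 0.6654)   # 2 3 3 2
#' @export
dissimilarity_density <- function(D, r, active = seq_len(nrow(D))) {
  D <- unclass_diss(D)
  if (!is.finite(r) || r <= 0) stop("'r' must be a positive radius")
  if (length(active) < 1L) stop("'active' must be non-empty")
  as.integer(rowSums(D[active, active, drop = FALSE] <= r))
}

#' Candidate-cluster average dissimilarity (alpha)
#'
#' The candidate cluster of point \code{i} is the set
#' \code{N(i) = \{j in active : d_ij <= r\}} (including \code{i} itself).
#' Alpha is the average pairwise dissimilarity among its \code{m}
#' members, \code{sum(d[N, N]) / m^2}; small alpha means a compact
#' candidate cluster. A singleton candidate cluster has alpha 0.
#'
#' @inheritParams dissimilarity_density
#' @param i Index (into the full matrix) of the point under consideration;
#'   must be a member of \code{active}.
#' @return The scalar alpha for point \code{i}.
#' @export
candidate_alpha <- function(D, r, i, active = seq_len(nrow(D))) {
  D <- unclass_diss(D)
  if (!i %in% active) stop("'i' must belong to 'active'")
  nb <- active[D[i, active] <= r]
  m <- length(nb)
  if (m <= 1L) return(0)
  sum(D[nb, nb]) / m^2
}

#' Candidate-cluster separation (s)
#'
#' The density-peaks-style separation statistic: the dissimilarity from
#' point \code{i} to its nearest active point of strictly higher density;
#' if no active point has higher density (\code{i} is a density peak),
#' the maximum dissimilarity from \code{i} to any other active point.
#' For a singleton active set, 0.
#'
#' @inheritParams candidate_alpha
#' @param rho Density vector aligned with \code{active}, from
#'   \code{\link{dissimilarity_density}}.
#' @return The scalar s for point \code{i}.
#' @export
candidate_s <- function(D, rho, i, active = seq_len(nrow(D))) {
  D <- unclass_diss(D)
  pos <- match(i, active)
  if (is.na(pos)) stop("'i' must belong to 'active'")
  if (length(active) == 1L) return(0)
  others <- active[-pos]
  higher <- others[rho[-pos] > rho[pos]]
  if (length(higher)) min(D[i, higher]) else max(D[i, others])
}

#' Dissimilarity weights (omega)
#'
#' The centre-selection score \code{omega = rho * s / alpha}: dense,
#' compact (small alpha) and well-separated (large s) points score
#' highest and are chosen as initial centres. When \code{alpha = 0}
#' (singleton candidate cluster) the ratio is undefined and omega is set
#' to 0 so isolated points are selected last, or flagged as noise in
#' robust mode.
#'
#' @param rho,alpha,s Numeric vectors aligned on the same active subset.
#' @return Numeric vector of weights.
#' @export
dissimilarity_weight <- function(rho, alpha, s) {
  stopifnot(length(rho) == length(alpha), length(alpha) == length(s))
  w <- ifelse(alpha > 0, rho * s / alpha, 0)
  as.numeric(w)
}

#' First-centre selection
#'
#' The first initial centre is the active point of maximum density. Ties
#' are broken by the smallest within-radius dissimilarity sum
#' \code{sum(i) = sum of d_ij over active j with d_ij <= r}; remaining
#' ties by lowest index.
#'
#' @inheritParams dissimilarity_density
#' @param rho Density vector aligned with \code{active}.
#' @return The selected sample index (into the full matrix).
#' @export
select_first_center <- function(D, rho, r, active = seq_len(nrow(D))) {
  D <- unclass_diss(D)
  tied <- active[rho == max(rho)]
  if (length(tied) == 1L) return(tied)
  sums <- vapply(tied, function(i) {
    dij <- D[i, active]
    sum(dij[dij <= r])
  }, numeric(1))
  tied[which.min(sums)]  # which.min takes the first (lowest-index) minimum
}

#' Iterative selection of initial centres
#'
#' Runs the dissimilarity-density-dynamic-radius seeding loop. Round 1
#' computes densities on the full data set and picks the first centre by
#' maximum density (ties by minimal within-radius dissimilarity sum,
#' then lowest index). Each round the chosen centre and every active
#' point within radius \code{r} of it are removed, densities, alpha, s
#' and the weights omega are recomputed on the remaining points, and the
#' point of maximum omega (ties by lowest index) becomes the next
#' centre. The loop ends when no points remain; the number of centres
#' is the emergent cluster count K.
#'
#' In \code{mode = "robust"}, a remaining point with density 1 (no other
#' active point within \code{r}) is flagged as noise and removed without
#' becoming a centre; in \code{mode = "strict"} every point either joins
#' a centre's removal set or eventually becomes a centre itself, exactly
#' as the printed selection steps prescribe.
#'
#' The radius is a global property of the data set: \code{r} stays fixed
#' across rounds while the densities and weights are recomputed on the
#' shrinking active set.
#'
#' @param D Dissimilarity matrix (\code{"d3k_dissim"} or plain matrix).
#' @param r Positive dynamic radius, see \code{\link{dynamic_radius}}.
#' @param mode \code{"strict"} (the printed algorithm) or \code{"robust"}
#'   (density-1 points become noise, never centres).
#' @return An object of class \code{"d3k_seeding"}: a list with
#'   \describe{
#'     \item{centers}{ordered integer vector of selected sample indices}
#'     \item{k}{emergent number of clusters, \code{length(centers)}}
#'     \item{rho, alpha, s, omega}{length-n traces holding each point's
#'       value at its last evaluation (the round in which it was removed)}
#'     \item{noise}{logical length-n vector, TRUE for points flagged as
#'       noise (robust mode only)}
#'     \item{removal_round}{integer length-n vector, the round in which
#'       each point left the active set}
#'     \item{omega_at_selection}{omega of each centre when it was chosen
#'       (NA for the first centre, which is chosen by density)}
#'     \item{r, mode}{the inputs}
#'   }
#' @examples
#' D <- dissimilarity_matrix(cbind(c(0, 1, 4, 5)))
#' select_centers(D, r = 0.6654)$centers   # 2 4
#' @export
select_centers <- function(D, r, mode = c("strict", "robust")) {
  mode <- match.arg(mode)
  D <- unclass_diss(D)
  n <- nrow(D)
  if (!is.finite(r) || r <= 0)
    stop("seeding needs a positive radius r (duplicate-only data give r = 0)")

  active <- seq_len(n)
  centers <- integer(0)
  omega_sel <- numeric(0)
  rho_tr <- alpha_tr <- s_tr <- omega_tr <- rep(NA_real_, n)
  noise <- logical(n)
  removal_round <- rep(NA_integer_, n)
  round <- 0L

  while (length(active)) {
    round <- round + 1L
    rho <- dissimilarity_density(D, r, active)

    if (mode == "robust") {
      iso <- rho == 1L
      if (any(iso)) {
        # density-1 points are within r of nobody else, so dropping them
        # leaves the remaining densities unchanged
        idx <- active[iso]
        rho_tr[idx] <- 1
        alpha_tr[idx] <- 0
        s_tr[idx] <- vapply(idx, function(i) candidate_s(D, rho, i, active),
                            numeric(1))
        omega_tr[idx] <- 0
        noise[idx] <- TRUE
        removal_round[idx] <- round
        active <- active[!iso]
        rho <- rho[!iso]
        if (!length(active)) {
          if (!length(centers))
            stop(paste("every point is isolated at this radius; no centre",
                       "can be selected in robust mode (try strict mode or",
                       "a larger radius)"))
          break
        }
      }
    }

    alpha <- vapply(active, function(i) candidate_alpha(D, r, i, active),
                    numeric(1))
    s <- vapply(active, function(i) candidate_s(D, rho, i, active),
                numeric(1))
    omega <- dissimilarity_weight(rho, alpha, s)
    rho_tr[active] <- rho
    alpha_tr[active] <- alpha
    s_tr[active] <- s
    omega_tr[active] <- omega

    if (!length(centers)) {
      ctr <- select_first_center(D, rho, r, active)
      omega_sel <- c(omega_sel, NA_real_)
    } else {
      ctr <- active[which.max(omega)]  # first maximum = lowest index
      omega_sel <- c(omega_sel, max(omega))
    }
    centers <- c(centers, ctr)
    removed <- active[D[ctr, active] <= r]   # always includes ctr itself
    removal_round[removed] <- round
    active <- setdiff(active, removed)
  }

  structure(list(centers = centers, k = length(centers),
                 rho = rho_tr, alpha = alpha_tr, s = s_tr, omega = omega_tr,
                 noise = noise, removal_round = removal_round,
                 omega_at_selection = omega_sel, r = r, mode = mode),
            class = "d3k_seeding")
}

#' @export
print.d3k_seeding <- function(x, ...) {
  cat(sprintf("D3K seeding (%s mode): %d centre(s) at radius r = %.6g\n",
              x$mode, x$k, x$r))
  cat("  centres (selection order):", paste(x$centers, collapse = ", "), "\n")
  if (any(x$noise))
    cat(sprintf("  %d point(s) flagged as noise\n", sum(x$noise)))
  invisible(x)
}

unclass_diss <- function(D) {
  D <- unclass(D)
  attributes(D)[setdiff(names(attributes(D)), c("dim", "dimnames"))] <- NULL
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("'D' must be a square dissimilarity matrix")
  D
}
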
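#' Select dynamically expressed genes across the shoot ontogeny
#'
#' A gene is dynamic when its floored expression changes at least
#' `fold`-fold in some two-way comparison among the named tissues, i.e.
#' `max(x_f) / min(x_f) >= fold` with `x_f = pmax(x, floor_rpm)`. The
#' floor stabilizes ratios for genes absent from some tissues.
#'
#' @param profiles Gene x domain RPM matrix.
#' @param tissues Ordered tissue subset (default meristem through P3).
#' @param fold Fold-change threshold (inclusive, default 2).
#' @param floor_rpm Expression floor in RPM before ratio computation.
#' @return Character vector of dynamic gene identifiers.
#' @export
select_dynamic_genes <- function(profiles, tissues = ontogeny_tissues(),
                                 fold = 2, floor_rpm = 1) {
  if (length(tissues) == 0) stop("empty tissue list")
  if (!all(tissues %in% colnames(profiles)))
    stop("tissues missing from profiles: ",
         paste(setdiff(tissues, colnames(profiles)), collapse = ", "))
  x <- pmax(profiles[, tissues, drop = FALSE], floor_rpm)
  ratio <- apply(x, 1, max) / apply(x, 1, min)
  rownames(profiles)[ratio >= fold]
}

#' CAST clustering on Spearman profile similarity
#'
#' Cluster Affinity Search Technique over the pairwise Spearman rank
#' correlation of tissue profiles. While unassigned genes remain, a new
#' cluster is opened with the unassigned gene of maximal total similarity
#' to the other unassigned genes (ties to the lexicographically smallest
#' identifier), then ADD steps (move in the unassigned gene with highest
#' mean similarity to current members while that mean is >= `t`) and
#' REMOVE steps (drop the member with lowest mean similarity to the other
#' members while that mean is < `t`) alternate until stable, one gene at a
#' time with recomputation. The tie rules make the output canonical and
#' independent of input row order.
#'
#' @param mat Gene x tissue expression matrix (>= 2 genes).
#' @param t Affinity threshold in (0, 1] on the mean Spearman correlation.
#' @return List of class `cast_result`: `clusters` (list of gene-id
#'   vectors, in creation order), `assignments` (gene, cluster data
#'   frame), `t`, and the similarity matrix as attribute `similarity`.
#' @export
cast_cluster <- function(mat, t = 0.8) {
  if (t <= 0 || t > 1) stop("affinity threshold t must be in (0, 1]")
  if (nrow(mat) < 1) stop("no genes to cluster")
  mat <- mat[order(rownames(mat)), , drop = FALSE]   # canonical order
  n <- nrow(mat)
  if (n == 1) {
    res <- list(clusters = list(rownames(mat)),
                assignments = data.frame(gene = rownames(mat),
                                         cluster = "C001",
                                         stringsAsFactors = FALSE),
                t = t)
    class(res) <- "cast_result"
    return(res)
  }
  S <- suppressWarnings(stats::cor(t(mat), method = "spearman"))
  if (any(is.na(S))) {
    warning("constant profiles give undefined Spearman similarity; ",
            "treated as 0")
    S[is.na(S)] <- 0
    diag(S) <- 1
  }
  unassigned <- rep(TRUE, n)
  utot <- rowSums(S) - 1               # similarity to other unassigned
  clusters <- list()
  guard <- 0L
  while (any(unassigned)) {
    U <- which(unassigned)
    seed <- U[which.max(utot[U])]      # first max = smallest id
    members <- seed
    unassigned[seed] <- FALSE
    utot <- utot - S[, seed]
    csum <- S[, seed]                  # similarity of all genes to members
    repeat {
      changed <- FALSE
      repeat {                         # ADD phase
        U <- which(unassigned)
        if (!length(U)) break
        avg <- csum[U] / length(members)
        b <- which.max(avg)
        if (avg[b] >= t) {
          g <- U[b]
          members <- c(members, g)
          unassigned[g] <- FALSE
          utot <- utot - S[, g]
          csum <- csum + S[, g]
          changed <- TRUE
        } else break
      }
      repeat {                         # REMOVE phase
        if (length(members) <= 1) break
        avgm <- (csum[members] - 1) / (length(members) - 1)
        wv <- which(avgm == min(avgm))
        wq <- wv[1]                    # smallest id among ties
        if (avgm[wq] < t) {
          g <- members[wq]
          members <- members[-wq]
          unassigned[g] <- TRUE
          utot <- utot + S[, g]
          csum <- csum - S[, g]
          changed <- TRUE
        } else break
      }
      guard <- guard + 1L
      if (!changed || guard > 100L * n) break
    }
    clusters[[length(clusters) + 1L]] <- rownames(mat)[sort(members)]
  }
  ids <- sprintf("C%03d", seq_along(clusters))
  names(clusters) <- ids
  asg <- data.frame(
    gene = unlist(clusters, use.names = FALSE),
    cluster = rep(ids, lengths(clusters)), stringsAsFactors = FALSE)
  res <- list(clusters = clusters, assignments = asg, t = t)
  attr(res, "similarity") <- S
  class(res) <- "cast_result"
  res
}

#' Classify a cluster's mean profile into a SAM-domain archetype
#'
#' Rules are evaluated in order on the cluster mean profile over
#' (meristem, Tip, P0, P1, P2, P3), rescaled to maximum 1:
#' OC (meristem peak, Tip and primordia low), CZ (Tip peak, later
#' primordia low), PZ (P0 peak, Tip low), core (meristem and Tip both
#' high, primordia low), then monotone leaf gradients by Spearman
#' correlation of the Tip->P3 series with ontogeny rank; anything else is
#' `other`. The numeric thresholds formalize the qualitative archetype
#' shapes and are exposed as arguments.
#'
#' @param m Named mean profile over the six ontogeny tissues.
#' @param low Low-expression threshold on the rescaled profile.
#' @param high High-expression threshold (core rule).
#' @param rho Spearman threshold for monotone leaf gradients.
#' @return One of "OC", "CZ", "PZ", "core", "leaf_up", "leaf_down",
#'   "other".
#' @export
classify_cluster_archetype <- function(m, low = 0.3, high = 0.8,
                                       rho = 0.9) {
  tis <- ontogeny_tissues()
  if (!all(tis %in% names(m))) stop("profile must cover ", toString(tis))
  m <- m[tis] / max(m[tis])
  P <- m[c("P0", "P1", "P2", "P3")]
  is_max <- function(d) m[[d]] >= 1 - 1e-12
  if (is_max("meristem") && m[["Tip"]] <= low && max(P) <= low)
    return("OC")
  if (is_max("Tip") && max(P[c("P1", "P2", "P3")]) <= low) return("CZ")
  if (is_max("P0") && m[["Tip"]] <= low) return("PZ")
  if (m[["meristem"]] >= high && m[["Tip"]] >= high && max(P) <= low)
    return("core")
  r <- suppressWarnings(
    stats::cor(m[.leaf_series()], seq_along(.leaf_series()),
               method = "spearman"))
  if (!is.na(r) && r >= rho) return("leaf_up")
  if (!is.na(r) && r <= -rho) return("leaf_down")
  "other"
}

#' Archetype labels and composite profiles for a cluster set
#'
#' The composite profile of a cluster is the mean of its members'
#' max-rescaled tissue profiles (each gene scaled to peak 1 first), so
#' the composite reflects the shared shape rather than the few most
#' highly expressed members.
#'
#' @param cast A [cast_cluster()] result.
#' @param profiles Gene x domain RPM matrix covering the clustered genes.
#' @param min_size Clusters below this size are labelled but flagged.
#' @return Data frame: cluster, size, archetype, plus one column per
#'   ontogeny tissue with the cluster composite profile.
#' @export
cluster_archetypes <- function(cast, profiles, min_size = 1) {
  tis <- ontogeny_tissues()
  rows <- lapply(names(cast$clusters), function(id) {
    g <- cast$clusters[[id]]
    x <- profiles[g, tis, drop = FALSE]
    m <- colMeans(x / pmax(apply(x, 1, max), 1e-12))
    data.frame(cluster = id, size = length(g),
               archetype = classify_cluster_archetype(m),
               t(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$small <- out$size < min_size
  out
}
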
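BASES <- c("A", "C", "G", "T")

# Construct a pwm_model: pseudocount-free probability matrix plus log2
# odds against the background. Threshold fields are filled by
# calibrate_threshold().
new_pwm <- function(id, mat, family = NA_character_,
                    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                    pseudocount = 0) {
  mat <- as.matrix(mat)
  colnames(mat) <- BASES
  if (any(abs(rowSums(mat) - 1) > 1e-3))
    stop("PWM '", id, "': probability rows do not sum to 1")
  if (pseudocount > 0)
    mat <- (1 - 4 * pseudocount) * mat + pseudocount
  mat <- mat / rowSums(mat)
  bg <- background / sum(background)
  lo <- log2(sweep(mat, 2, bg, `/`))
  structure(list(id = id, family = family, width = nrow(mat),
                 mat = mat, background = bg, logodds = lo,
                 threshold = NA_real_, match_p = NA_real_),
            class = "pwm_model")
}

#' Read PWMs from a MEME minimal motif file
#'
#' Parses the MEME minimal motif format (MOTIF blocks with
#' letter-probability matrices, optional background frequency line),
#' mixes in a pseudocount (`M <- (1 - 4 eps) M + eps`) and attaches
#' family labels from an optional side table.
#'
#' @param path MEME-format file.
#' @param pseudocount Pseudocount epsilon (default 0.01).
#' @param background Named A/C/G/T frequencies; defaults to the file's
#'   background line, else uniform.
#' @param family_map Optional data frame (`pwm`, `family`).
#' @return Named list of `pwm_model` objects.
#' @export
read_pwms <- function(path, pseudocount = 0.01, background = NULL,
                      family_map = NULL) {
  lines <- readLines(path)
  bg <- background
  bgl <- grep("^Background letter frequencies", lines)
  if (is.null(bg) && length(bgl)) {
    tok <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
    bg <- stats::setNames(as.numeric(tok[c(2, 4, 6, 8)]), tok[c(1, 3, 5, 7)])
    bg <- bg[BASES]
  }
  if (is.null(bg)) bg <- stats::setNames(rep(0.25, 4), BASES)
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF records in ", path)
  pwms <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- s + 1
    while (h <= length(lines) &&
           !grepl("^letter-probability matrix", lines[h])) h <- h + 1
    if (h > length(lines))
      stop("PWM '", id, "': missing letter-probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    if (is.na(w)) stop("PWM '", id, "': cannot parse width")
    rows <- lines[(h + 1):(h + w)]
    mat <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(4), USE.NAMES = FALSE))
    fam <- NA_character_
    if (!is.null(family_map)) {
      m <- match(id, family_map$pwm)
      if (!is.na(m)) fam <- family_map$family[m]
    }
    pwms[[id]] <- new_pwm(id, mat, family = fam, background = bg,
                          pseudocount = pseudocount)
  }
  pwms
}

#' Write PWMs to a MEME minimal motif file
#'
#' @param pwms Named list of `pwm_model` objects.
#' @param path Output file.
#' @export
write_pwms <- function(pwms, path) {
  bg <- pwms[[1]]$background
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "strands: + -", "", "Background letter frequencies",
           paste(sprintf("%s %.6f", BASES, bg), collapse = " "), "")
  for (p in pwms) {
    out <- c(out, paste("MOTIF", p$id),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     p$width),
             apply(p$mat, 1, function(r) paste(sprintf("%.6f", r),
                                               collapse = " ")),
             "")
  }
  writeLines(out, path)
}

#' Mononucleotide background frequencies of a genome
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return Named A/C/G/T frequency vector.
#' @export
background_frequencies <- function(genome) {
  f <- colSums(Biostrings::letterFrequency(genome, BASES))
  f / sum(f)
}

#' Calibrate a PWM match threshold by exact score-distribution DP
#'
#' Computes the exact distribution of the log-odds score of a random
#' background sequence of the motif's width by position-wise dynamic
#' programming over a discretized score grid, and sets the threshold to
#' the smallest score whose upper-tail probability is <= `p_value`. The
#' per-position score contributions are rounded to the grid, so DP tail
#' probabilities are exact at bin resolution.
#'
#' @param pwm A `pwm_model`.
#' @param p_value Per-window match probability under the background
#'   (must lie in (0, 0.5)).
#' @param bins Score grid resolution (default 1e4).
#' @return The input `pwm_model` with `threshold` (log2-odds scale) and
#'   `match_p` filled in, plus attribute `score_dist` (data frame:
#'   score, prob, tail) and `theta_idx`.
#' @export
calibrate_threshold <- function(pwm, p_value = 1e-4, bins = 1e4) {
  if (p_value <= 0 || p_value >= 0.5)
    stop("p_value must lie in (0, 0.5)")
  if (any(!is.finite(pwm$logodds))) stop("non-finite log-odds")
  d <- pwm_score_grid(pwm, bins)
  prob <- rep(0, d$range + 1L)          # index 0..range
  prob[1] <- 1
  for (i in seq_len(pwm$width)) {
    nxt <- rep(0, d$range + 1L)
    for (b in seq_len(4)) {
      off <- d$idx[i, b]
      src <- which(prob > 0)
      nxt[src + off] <- nxt[src + off] + prob[src] * pwm$background[b]
    }
    prob <- nxt
  }
  tail <- rev(cumsum(rev(prob)))
  ok <- which(tail <= p_value)
  if (!length(ok)) {
    theta_idx <- d$range + 1L           # unreachable: nothing matches
    mp <- 0
  } else {
    theta_idx <- min(ok) - 1L           # 0-based grid index
    mp <- tail[theta_idx + 1L]
  }
  # half-bin guard: exact scores rounding into bin theta_idx must pass
  pwm$threshold <- d$min_score + (theta_idx - 0.5) / d$scale
  pwm$match_p <- mp
  attr(pwm, "score_dist") <- data.frame(
    score = d$min_score + (seq_along(prob) - 1L) / d$scale,
    prob = prob, tail = tail)
  attr(pwm, "theta_idx") <- theta_idx
  pwm
}

# Shared discretization of per-position log-odds contributions.
pwm_score_grid <- function(pwm, bins) {
  lo <- pwm$logodds
  min_s <- sum(apply(lo, 1, min))
  max_s <- sum(apply(lo, 1, max))
  if (max_s <= min_s) stop("degenerate score range")
  scale <- (bins - 1) / (max_s - min_s)
  pmin <- apply(lo, 1, min)
  idx <- round(sweep(lo, 1, pmin) * scale)
  storage.mode(idx) <- "integer"
  list(idx = idx, scale = scale, min_score = sum(pmin),
       range = sum(apply(idx, 1, max)))
}

#' Scan a promoter sequence for PWM matches on both strands
#'
#' Slides the motif over both strands of the sequence; a window matches
#' when its summed log-odds score reaches the calibrated threshold.
#' Overlapping matches count separately; windows containing ambiguous
#' bases are skipped. Positions are promoter-relative (1-based window
#' start on the forward promoter sequence).
#'
#' @param pwm A `pwm_model` with calibrated `threshold` (or supply
#'   `theta`).
#' @param sequence Promoter sequence (character or DNAString).
#' @param theta Optional threshold override (log2-odds).
#' @return Data frame: position, strand, score. Zero rows when no match.
#' @export
scan_promoter <- function(pwm, sequence, theta = pwm$threshold) {
  if (is.na(theta)) stop("threshold not calibrated; run calibrate_threshold")
  code <- .encode_seq(as.character(sequence))
  w <- pwm$width
  n <- length(code) - w + 1L
  empty <- data.frame(position = integer(0), strand = character(0),
                      score = numeric(0))
  if (n < 1) return(empty)
  lo_rc <- pwm$logodds[w:1, c("T", "G", "C", "A"), drop = FALSE]
  colnames(lo_rc) <- BASES
  hit <- function(lo) {
    sc <- rep(0, n)
    for (i in seq_len(w)) {
      v <- lo[i, code[i:(i + n - 1L)]]
      sc <- sc + v                     # NA for ambiguous bases
    }
    sc
  }
  sp <- hit(pwm$logodds)
  sm <- hit(lo_rc)
  ip <- which(!is.na(sp) & sp >= theta)
  im <- which(!is.na(sm) & sm >= theta)
  res <- rbind(
    data.frame(position = ip, strand = rep("+", length(ip)),
               score = sp[ip]),
    data.frame(position = im, strand = rep("-", length(im)),
               score = sm[im]))
  res[order(res$position, res$strand), , drop = FALSE]
}

# lean both-strand match counter on a pre-encoded sequence
.count_matches <- function(code, lo, lo_rc, w, theta) {
  n <- length(code) - w + 1L
  if (n < 1L) return(0L)
  sp <- numeric(n); sm <- numeric(n)
  for (i in seq_len(w)) {
    idx <- code[i:(i + n - 1L)]
    sp <- sp + lo[i, idx]
    sm <- sm + lo_rc[i, idx]
  }
  sum(sp >= theta, na.rm = TRUE) + sum(sm >= theta, na.rm = TRUE)
}

.encode_seq <- function(s) {
  v <- utf8ToInt(toupper(s))
  code <- rep(NA_integer_, length(v))
  code[v == 65L] <- 1L; code[v == 67L] <- 2L
  code[v == 71L] <- 3L; code[v == 84L] <- 4L
  code
}
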
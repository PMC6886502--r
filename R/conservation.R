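#' Built-in Arabidopsis conservation rules
#'
#' Per-class rules over relative expression across nine Arabidopsis shoot
#' domains (AtHB8 xylem, S17shoot phloem, WUS organizing centre, CLV3
#' central zone, FIL organ primordia, HDG4 meristematic L2, HMG
#' meristematic L1, KAN1 outer peripheral zone, LAS organ boundary).
#' Each rule lists domains excluded before renormalization, defining
#' domains (relative expression strictly > `define_gt`) and domains that
#' must stay strictly below `low_lt`. The comparatively lax thresholds
#' accommodate the partial overlap of the reference domains.
#'
#' @param define_gt Defining-domain threshold (default 0.25).
#' @param low_lt Low-domain threshold (default 0.20).
#' @return Named list of rules (exclude, define, low, thresholds).
#' @export
conservation_rules <- function(define_gt = 0.25, low_lt = 0.20) {
  if (define_gt <= 0 || define_gt >= 1 || low_lt <= 0 || low_lt >= 1)
    stop("thresholds must lie in (0, 1)")
  all_dom <- c("AtHB8", "S17shoot", "WUS", "CLV3", "FIL", "HDG4",
               "HMG", "KAN1", "LAS")
  mk <- function(exclude, define, low) {
    if (length(intersect(define, low)))
      stop("defining and low domain sets must be disjoint")
    list(exclude = exclude, define = define, low = low,
         define_gt = define_gt, low_lt = low_lt, domains = all_dom)
  }
  list(
    vasculature = mk(character(0), c("AtHB8", "S17shoot"),
                     setdiff(all_dom, c("AtHB8", "S17shoot"))),
    organ_initiation = mk(c("S17shoot", "AtHB8"), c("FIL", "LAS"),
                          c("KAN1", "CLV3", "WUS")),
    OC = mk(c("S17shoot", "AtHB8"), "WUS",
            c("FIL", "KAN1", "LAS", "HMG", "HDG4")),
    CZ = mk(c("S17shoot", "AtHB8"), "CLV3", c("FIL", "KAN1", "LAS")))
}

# Does one reference profile satisfy a class rule?  The profile is
# renormalized after dropping the rule's excluded domains.
.rule_satisfied <- function(profile, rule) {
  keep <- setdiff(names(profile), rule$exclude)
  p <- profile[keep]
  s <- sum(p)
  if (!is.finite(s) || s <= 0) return(FALSE)
  p <- p / s
  any(p[intersect(rule$define, keep)] > rule$define_gt) &&
    all(p[intersect(rule$low, keep)] < rule$low_lt)
}

#' Cross-species conservation classification of domain-specific genes
#'
#' For each maize gene, applies the class's expression rule to its
#' Arabidopsis ortholog's reference domain profile; when every ortholog
#' fails, near-paralogs are tested (first-success over identifier-sorted
#' lists, so the call is order-independent).
#'
#' @param genes Maize gene identifiers.
#' @param ortholog_map Data frame: maize_gene, at_gene, relation
#'   ("ortholog" or "paralog").
#' @param reference Matrix/data frame of relative expression, Arabidopsis
#'   genes x reference domains.
#' @param class Conservation class, one of
#'   `names(conservation_rules())`.
#' @param rules Rule set (default [conservation_rules()]).
#' @return Character vector per gene: "ortholog-conserved",
#'   "paralog-conserved", "not-conserved" or "no-ortholog".
#' @export
conservation_classify <- function(genes, ortholog_map, reference,
                                  class, rules = conservation_rules()) {
  if (!class %in% names(rules))
    stop("unknown conservation class: ", class)
  rule <- rules[[class]]
  reference <- as.matrix(reference)
  test_set <- function(at_genes) {
    for (ag in sort(at_genes)) {
      if (!ag %in% rownames(reference)) next
      if (.rule_satisfied(reference[ag, ], rule)) return(TRUE)
    }
    FALSE
  }
  vapply(genes, function(g) {
    hits <- ortholog_map[ortholog_map$maize_gene == g, , drop = FALSE]
    if (!nrow(hits)) return("no-ortholog")
    orth <- hits$at_gene[hits$relation == "ortholog"]
    if (length(orth) && test_set(orth)) return("ortholog-conserved")
    par <- hits$at_gene[hits$relation == "paralog"]
    if (length(par) && test_set(par)) return("paralog-conserved")
    "not-conserved"
  }, character(1))
}
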
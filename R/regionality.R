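#' The ordered anteroposterior CNS axis
#'
#' The CNS domains ordered head to tail — forebrain (FB), midbrain (MB),
#' hindbrain (HB), cervical (CSC), thoracic (TSC) and lumbar (LSC) spinal
#' cord, and the caudal SC — each split into an anterior and a posterior
#' half so that boundary inferences like "anterior CSC" can be represented.
#' Positions on the axis are integer *ranks*: `2 * domain - 1` for the
#' anterior half, `2 * domain` for the posterior half.
#'
#' @return A data frame with columns `domain`, `half`, `rank`.
#' @export
ap_axis <- function() {
  domains <- c("FB", "MB", "HB", "CSC", "TSC", "LSC", "caudal")
  data.frame(domain = rep(domains, each = 2L),
             half = rep(c("anterior", "posterior"), times = length(domains)),
             rank = seq_len(2L * length(domains)),
             stringsAsFactors = FALSE)
}

ap_rank <- function(domain, half) {
  ax <- ap_axis()
  ax$rank[ax$domain == domain & ax$half == half]
}

ap_label <- function(rank) {
  ax <- ap_axis()
  row <- ax[ax$rank == rank, ]
  paste(row$half, row$domain)
}

#' The Hox / brain-marker regional code
#'
#' The lookup table behind [classify_ap()]. Brain markers are keyed to
#' their diagnostic anterior limit (the domain they pin down when more
#' anterior markers are absent): Foxg1 marks the FB; Otx2 spans FB and MB,
#' so absent Foxg1 it places the anterior limit at the MB; En2 spans the
#' posterior MB and anterior HB. Hox genes are grouped in classes by the
#' domain holding their anterior expression boundary: the HB class
#' (Hoxa1--a4, Hoxb1--b4), the CSC class (Hoxa5, Hoxb5, Hoxb6; Hoxa5's
#' boundary lies anterior to Hoxb5's), the TSC class (Hoxa6, a7, a9, a10,
#' Hoxb7--b9 with boundaries near the CSC/TSC junction, and Hoxc9), the
#' LSC-and-posterior genes Hoxc10 and Hoxc11, and the caudal genes Hoxa13
#' and Hoxb13.
#'
#' @return A list with elements `brain` (data frame gene / anterior rank /
#'   posterior rank) and `classes` (named list of gene vectors, ordered
#'   anterior to posterior, with the boundary domain of each class as an
#'   attribute).
#' @export
hox_code <- function() {
  brain <- data.frame(
    gene = c("Foxg1", "Otx2", "En2"),
    anterior = c(ap_rank("FB", "anterior"),
                 ap_rank("MB", "anterior"),
                 ap_rank("MB", "posterior")),
    posterior = c(ap_rank("FB", "posterior"),
                  ap_rank("MB", "posterior"),
                  ap_rank("HB", "anterior")),
    stringsAsFactors = FALSE)
  classes <- list(
    HB  = c("Hoxa1", "Hoxa2", "Hoxa3", "Hoxa4",
            "Hoxb1", "Hoxb2", "Hoxb3", "Hoxb4"),
    CSC = c("Hoxa5", "Hoxb5", "Hoxb6"),
    TSC = c("Hoxa6", "Hoxa7", "Hoxa9", "Hoxa10",
            "Hoxb7", "Hoxb8", "Hoxb9", "Hoxc9"),
    LSC = c("Hoxc10", "Hoxc11"),
    caudal = c("Hoxa13", "Hoxb13"))
  attr(classes, "boundary_domain") <-
    c(HB = "HB", CSC = "CSC", TSC = "TSC", LSC = "LSC", caudal = "caudal")
  list(brain = brain, classes = classes)
}

#' Bundled expression-tier code for the six EpiSC-derived NSC lines
#'
#' Tier labels (off / low / high) of the brain markers and Hox genes in
#' the six neural stem cell lines XN4, XN1, KN3, KN1, CN1 and CN4, as
#' assessed from their bulk expression profiles. Used as the default input
#' of [simulate_bulk_profiles()] and as the worked classification example.
#'
#' @return sample x gene character matrix of tiers.
#' @export
nsc_line_code <- function() {
  code <- hox_code()
  genes <- c(code$brain$gene, unlist(code$classes, use.names = FALSE))
  lines <- c("XN4", "XN1", "KN3", "KN1", "CN1", "CN4")
  m <- matrix("off", nrow = length(lines), ncol = length(genes),
              dimnames = list(lines, genes))
  hb <- code$classes$HB
  set <- function(line, g, tier) m[line, g] <<- tier
  # XN4: forebrain line; Foxg1 high, traces of Otx2/En2, no Hox.
  set("XN4", "Foxg1", "high"); set("XN4", c("Otx2", "En2"), "low")
  # XN1: Otx2/En2 with HB-class Hox and Hoxa5 (not Hoxb5).
  set("XN1", c("Otx2", "En2"), "high")
  set("XN1", c(hb, "Hoxa5"), "high")
  # KN3: En2 plus HB-class Hoxa genes; CSC and TSC classes at low level.
  set("KN3", "En2", "high")
  set("KN3", c("Hoxa1", "Hoxa2", "Hoxa3", "Hoxa4"), "high")
  set("KN3", c("Hoxa5", "Hoxa6", "Hoxa7"), "low")
  # KN1: no brain markers; HB + CSC classes and Hoxa6-7, Hoxb7-9 high,
  # Hoxa9/a10 absent.
  set("KN1", c(hb, "Hoxa5", "Hoxb5", "Hoxb6"), "high")
  set("KN1", c("Hoxa6", "Hoxa7", "Hoxb7", "Hoxb8", "Hoxb9"), "high")
  # CN1/CN4: HB, CSC, TSC classes including Hoxa9/a10 and Hoxc9;
  # no Hoxc10/c11.
  for (ln in c("CN1", "CN4")) {
    set(ln, c(hb, "Hoxa5", "Hoxb5", "Hoxb6"), "high")
    set(ln, c("Hoxa6", "Hoxa7", "Hoxa9", "Hoxa10",
              "Hoxb7", "Hoxb8", "Hoxb9", "Hoxc9"), "high")
  }
  m
}

#' Reference regional-coverage calls for the six NSC lines
#'
#' The anteroposterior coverage assessments reported for the six lines,
#' encoded on the half-domain rank scale of [ap_axis()]: XN4 is a
#' forebrain line (with low-tier extension toward MB/HB); XN1 covers MB to
#' the anterior CSC; KN3 covers an HB core with a low-tier posterior
#' extension; KN1 the posterior HB/CSC to the anterior TSC; CN1 and CN4
#' reach their posterior limit in the TSC. No line reaches the LSC.
#'
#' @return Data frame with `line`, `core_anterior`, `core_posterior`,
#'   `extended_posterior` ranks.
#' @export
nsc_reference_calls <- function() {
  r <- ap_rank
  data.frame(
    line = c("XN4", "XN1", "KN3", "KN1", "CN1", "CN4"),
    core_anterior = c(r("FB", "anterior"), r("MB", "anterior"),
                      r("MB", "posterior"), r("HB", "posterior"),
                      r("HB", "posterior"), r("HB", "posterior")),
    core_posterior = c(r("FB", "posterior"), r("CSC", "anterior"),
                       r("HB", "posterior"), r("TSC", "anterior"),
                       r("TSC", "posterior"), r("TSC", "posterior")),
    extended_posterior = c(r("HB", "anterior"), r("CSC", "anterior"),
                           r("TSC", "anterior"), r("TSC", "anterior"),
                           r("TSC", "posterior"), r("TSC", "posterior")),
    stringsAsFactors = FALSE)
}

#' Max-normalise a bulk expression table
#'
#' Replicate measurements of each sample are averaged, then each gene is
#' divided by its maximum over a reference sample set so that the highest
#' expression equals 1.0. The default reference is all samples; passing
#' e.g. only the embryo-portion samples reproduces the variant in which
#' cell-line values may exceed 1. Genes whose reference maximum is zero are
#' flagged as not expressed (left at zero, recorded in the
#' `"not_expressed"` attribute) rather than divided.
#'
#' Replicate columns are recognised by a trailing `_<number>` in the column
#' name (`FB_1`, `FB_2` average into sample `FB`); columns without the
#' suffix are treated as single-replicate samples, so the function is
#' idempotent on its own output.
#'
#' @param table genes x sample_replicate numeric matrix.
#' @param reference_samples samples over which the per-gene max is taken
#'   (default all).
#' @return genes x samples matrix of normalised values with attribute
#'   `not_expressed`.
#' @export
max_normalize <- function(table, reference_samples = NULL) {
  if (is.null(dim(table))) stop("`table` must be a genes x columns matrix")
  if (min(table) < 0) stop("intensities must be non-negative")
  sample_of <- sub("_[0-9]+$", "", colnames(table))
  samples <- unique(sample_of)
  avg <- sapply(samples, function(s)
    rowMeans(table[, sample_of == s, drop = FALSE]))
  if (is.null(dim(avg))) avg <- matrix(avg, nrow = 1,
                                       dimnames = list(rownames(table), samples))
  if (is.null(reference_samples)) reference_samples <- samples
  missing <- setdiff(reference_samples, samples)
  if (length(missing))
    stop("reference sample(s) not in table: ", paste(missing, collapse = ", "))
  ref_max <- apply(avg[, reference_samples, drop = FALSE], 1L, max)
  flagged <- rownames(avg)[ref_max <= 0]
  scale <- ifelse(ref_max > 0, ref_max, 1)
  out <- avg / scale
  attr(out, "not_expressed") <- flagged
  out
}

#' Bin normalised expression values into tiers
#'
#' Deterministic three-tier binning of max-normalised values:
#' `off` below `thresholds[1]`, `low` from `thresholds[1]` (inclusive) up
#' to `thresholds[2]` (exclusive), `high` at or above `thresholds[2]`.
#' Defaults 0.1 and 0.5.
#'
#' @param x numeric vector/matrix of normalised values, >= 0.
#' @param thresholds length-2 increasing numeric vector.
#' @return Character vector/matrix of `"off"`, `"low"`, `"high"`.
#' @export
bin_tiers <- function(x, thresholds = c(0.1, 0.5)) {
  if (any(x < 0, na.rm = TRUE)) stop("normalised values must be >= 0")
  if (length(thresholds) != 2L || diff(thresholds) <= 0 || thresholds[1] <= 0)
    stop("`thresholds` must be two increasing positive numbers")
  tier <- ifelse(x >= thresholds[2], "high",
                 ifelse(x >= thresholds[1], "low", "off"))
  if (!is.null(dim(x))) dim(tier) <- dim(x)
  dimnames(tier) <- dimnames(x)
  tier
}

tier_num <- function(tiers) {
  lv <- c(off = 0L, low = 1L, high = 2L)
  out <- lv[tiers]
  out[is.na(out)] <- 0L
  names(out) <- names(tiers)
  out
}

#' Assign anteroposterior regional coverage from an expression-tier profile
#'
#' Implements the Hox-code assessment of a single sample. The *core*
#' interval is supported by high-tier markers, the *extended* interval adds
#' low-tier evidence. Rules, applied at each evidence level:
#'
#' * Anterior limit: the most anterior diagnostic rank among expressed
#'   brain markers (Foxg1 -> anterior FB; Otx2 -> anterior MB; En2 ->
#'   posterior MB). With no brain marker expressed, the posterior half of
#'   the most anterior expressed Hox class's boundary domain (an HB-class
#'   profile without brain markers starts at the posterior HB).
#' * Posterior limit: the furthest of the expressed brain markers'
#'   posterior spans and the boundary domain of the most posterior
#'   expressed Hox class, refined by three half-qualifier inferences:
#'   Hoxa5 as the sole CSC-class evidence (without Hoxb5/Hoxb6) caps the
#'   CSC class at the *anterior* CSC;
#'   a TSC-class profile lacking Hoxa9/Hoxa10 stops at the *anterior* TSC;
#'   Hoxc9 without Hoxc10 keeps the posterior limit within the TSC.
#' * A profile with no marker at or above the evidence level is
#'   *undetermined*.
#'
#' Genes absent from the profile are treated as off (and listed in the
#' result); extra genes are ignored.
#'
#' @param tiers named character vector of tiers (`off`/`low`/`high`) for
#'   one sample, e.g. one row of [bin_tiers()] output.
#' @param code regional code from [hox_code()].
#' @param sample optional sample label carried into the result.
#' @return An object of class `region_call`: list with `sample`, `core`
#'   and `extended` (each `c(anterior, posterior)` ranks or `NA`),
#'   `undetermined`, `evidence` (tier vector restricted to code genes),
#'   `missing_genes`.
#' @examples
#' tiers <- bin_tiers(setNames(c(1, 0.3, 0.2), c("Foxg1", "Otx2", "En2")))
#' classify_ap(tiers, sample = "XN4-like")
#' @export
classify_ap <- function(tiers, code = hox_code(), sample = NULL) {
  code_genes <- c(code$brain$gene, unlist(code$classes, use.names = FALSE))
  missing_genes <- setdiff(code_genes, names(tiers))
  full <- setNames(rep("off", length(code_genes)), code_genes)
  present <- intersect(names(tiers), code_genes)
  full[present] <- tiers[present]
  lvl <- tier_num(full)

  limits_at <- function(min_level) {
    expressed <- names(lvl)[lvl >= min_level]
    if (!length(expressed)) return(NULL)
    brain <- code$brain[code$brain$gene %in% expressed, , drop = FALSE]
    cls_expr <- vapply(code$classes, function(g) any(g %in% expressed),
                       logical(1))
    ant <- if (nrow(brain)) {
      min(brain$anterior)
    } else if (any(cls_expr)) {
      first <- names(cls_expr)[which(cls_expr)[1L]]
      dom <- attr(code$classes, "boundary_domain")[[first]]
      ap_rank(dom, "posterior")
    } else return(NULL)
    post_candidates <- if (nrow(brain)) max(brain$posterior) else -Inf
    if (any(cls_expr)) {
      last <- names(cls_expr)[max(which(cls_expr))]
      dom <- attr(code$classes, "boundary_domain")[[last]]
      g_lvl <- function(g) if (g %in% names(lvl)) lvl[[g]] else 0L
      half <- "posterior"
      # Hoxa5 as the sole CSC-class evidence (its boundary lies anterior
      # to Hoxb5's) supports only the anterior CSC
      other_csc <- setdiff(code$classes$CSC, "Hoxa5")
      if (last == "CSC" && g_lvl("Hoxa5") >= min_level &&
          !any(vapply(other_csc, g_lvl, integer(1)) >= min_level))
        half <- "anterior"
      if (last == "TSC" &&
          g_lvl("Hoxa9") < min_level && g_lvl("Hoxa10") < min_level)
        half <- "anterior"
      # Hoxc9 without Hoxc10: posterior limit stays within the TSC
      # (already the case when TSC is the last class; the LSC class being
      # unexpressed is what keeps the call out of the LSC).
      post_candidates <- c(post_candidates, ap_rank(dom, half))
    }
    post <- max(post_candidates)
    c(anterior = min(ant, post), posterior = post)
  }

  core <- limits_at(2L)
  ext <- limits_at(1L)
  if (!is.null(core) && !is.null(ext)) {
    ext["anterior"] <- min(ext["anterior"], core["anterior"])
    ext["posterior"] <- max(ext["posterior"], core["posterior"])
  }
  structure(list(sample = sample, core = core, extended = ext,
                 undetermined = is.null(ext),
                 evidence = full[lvl > 0],
                 missing_genes = missing_genes),
            class = "region_call")
}

#' @export
print.region_call <- function(x, ...) {
  hdr <- if (!is.null(x$sample)) paste0(" [", x$sample, "]") else ""
  if (x$undetermined) {
    cat(sprintf("Region call%s: undetermined (no expressed marker)\n", hdr))
    return(invisible(x))
  }
  fmt <- function(lim) {
    if (is.null(lim)) return("none (no high-tier marker)")
    if (lim["anterior"] == lim["posterior"]) return(ap_label(lim["anterior"]))
    paste(ap_label(lim["anterior"]), "to", ap_label(lim["posterior"]))
  }
  cat(sprintf("Region call%s\n", hdr))
  cat("  core:     ", fmt(x$core), "\n")
  cat("  extended: ", fmt(x$extended), "\n")
  if (length(x$missing_genes))
    cat(sprintf("  (%d code genes absent from profile, treated as off)\n",
                length(x$missing_genes)))
  invisible(x)
}

#' The dorsoventral neural-tube transcription-factor code
#'
#' Default class-defining TF sets of the dorsoventrally organised neural
#' tube: dorsal (Pax3, Pax7, Olig3), intermediate (Irx3, Irx5, Dbx1, Dbx2,
#' Pax6) and ventral (Nkx6-1, Nkx2-2, Olig2). The precise domain-by-domain
#' matrix varies between sources; this standard code is fully configurable.
#'
#' @return Named list of character vectors.
#' @export
dv_code <- function() {
  list(dorsal = c("Pax3", "Pax7", "Olig3"),
       intermediate = c("Irx3", "Irx5", "Dbx1", "Dbx2", "Pax6"),
       ventral = c("Nkx6-1", "Nkx2-2", "Olig2"))
}

#' Dorsoventral coherence check of a tier profile
#'
#' A dorsoventral identity is called only when every TF of some class's
#' set is expressed (at least low tier) *and* no isolated-marker conflict
#' is present. Two conflict rules are checked: Nkx2-2 expressed without
#' concurrent Nkx6-1 (rules out a coherent ventral identity), and
#' intermediate-class Irx expression unaccompanied by the dorsal
#' progenitor markers Pax3/Pax7. Otherwise the profile is `"ambiguous"`,
#' with the violated rules and any partially expressed classes reported.
#'
#' @param tiers named tier vector as in [classify_ap()].
#' @param code class-defining TF sets, as [dv_code()].
#' @return Object of class `dv_call`: list with `call` (one of the class
#'   names or `"ambiguous"`), `complete` (classes fully expressed),
#'   `violations` (character), `expressed` (genes at >= low tier).
#' @export
dv_coherence <- function(tiers, code = dv_code()) {
  if (!length(code) || any(!lengths(code)))
    stop("dorsoventral code must contain non-empty TF sets")
  allg <- unique(unlist(code))
  full <- setNames(rep("off", length(allg)), allg)
  present <- intersect(names(tiers), allg)
  full[present] <- tiers[present]
  lvl <- tier_num(full)
  expressed <- names(lvl)[lvl >= 1L]
  complete <- names(code)[vapply(code, function(g) all(g %in% expressed),
                                 logical(1))]
  violations <- character()
  if ("Nkx2-2" %in% expressed && !("Nkx6-1" %in% expressed))
    violations <- c(violations,
                    "Nkx2-2 expressed without concurrent Nkx6-1")
  irx <- intersect(c("Irx3", "Irx5"), expressed)
  if (length(irx) && !any(c("Pax3", "Pax7") %in% expressed))
    violations <- c(violations,
                    paste(paste(irx, collapse = "/"),
                          "expression unaccompanied by dorsal Pax3/Pax7"))
  call <- if (length(complete) == 1L && !length(violations))
    complete else "ambiguous"
  structure(list(call = call, complete = complete,
                 violations = violations, expressed = expressed),
            class = "dv_call")
}

#' @export
print.dv_call <- function(x, ...) {
  cat("Dorsoventral call:", x$call, "\n")
  if (length(x$complete))
    cat("  complete class set(s):", paste(x$complete, collapse = ", "), "\n")
  for (v in x$violations) cat("  rule violated:", v, "\n")
  invisible(x)
}
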
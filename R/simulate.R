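#' Parameters for the single-cell count simulator
#'
#' Defines the stochastic expression / capture model used by
#' [simulate_sc_counts()]. Each gene `g` is transcriptionally *on* in a cell
#' with probability `p_g`, independently across genes and cells. Each cell
#' `c` carries a depth multiplier `d_c` drawn from a log-normal distribution
#' (`meanlog = 0`), reflecting the highly variable per-cell read depth of
#' droplet/bead single-cell libraries. When a gene is on, the captured count
#' is Poisson with mean `d_c * m_g`, where `m_g` is the expected number of
#' captured molecules at unit depth; when it is off, the count is zero.
#'
#' @param n_cells number of cells to simulate.
#' @param genes character vector of gene names.
#' @param expr_prob named numeric vector, probability `p_g` in `[0, 1]` that
#'   a cell expresses each gene. Recycled if unnamed and scalar.
#' @param mean_capture named numeric vector of positive expected captured
#'   molecules `m_g` at unit depth (default 2 for every gene).
#' @param depth_sigma log-normal sigma of the per-cell depth multiplier;
#'   `0` gives constant depth 1. Default 0.8.
#' @param seed optional integer seed.
#' @return A list of class `sc_sim_params`.
#' @seealso [simulate_sc_counts()]
#' @export
sc_sim_params <- function(n_cells, genes, expr_prob,
                          mean_capture = 2, depth_sigma = 0.8,
                          seed = NULL) {
  if (length(genes) == 0L) stop("gene list must be non-empty")
  if (anyDuplicated(genes)) stop("gene names must be unique")
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) stop("n_cells must be >= 1")
  expr_prob <- expand_by_gene(expr_prob, genes, "expr_prob")
  if (any(expr_prob < 0 | expr_prob > 1))
    stop("expression probabilities must lie in [0, 1]")
  mean_capture <- expand_by_gene(mean_capture, genes, "mean_capture")
  if (any(mean_capture <= 0)) stop("mean_capture must be positive")
  if (depth_sigma < 0) stop("depth_sigma must be >= 0")
  structure(list(n_cells = n_cells, genes = as.character(genes),
                 expr_prob = expr_prob, mean_capture = mean_capture,
                 depth_sigma = depth_sigma, seed = seed),
            class = "sc_sim_params")
}

expand_by_gene <- function(x, genes, what) {
  if (length(x) == 1L && is.null(names(x)))
    return(setNames(rep(as.numeric(x), length(genes)), genes))
  if (is.null(names(x))) {
    if (length(x) != length(genes))
      stop(sprintf("`%s` must be named or match the gene list length", what))
    return(setNames(as.numeric(x), genes))
  }
  if (!all(genes %in% names(x)))
    stop(sprintf("`%s` missing entries for: %s", what,
                 paste(setdiff(genes, names(x)), collapse = ", ")))
  setNames(as.numeric(x[genes]), genes)
}

#' Simulate a single-cell count matrix under stochastic independent expression
#'
#' Draws a genes x cells integer count matrix under the model described in
#' [sc_sim_params()]: independent per-cell on/off expression with
#' probability `p_g`, a shared per-cell log-normal depth multiplier `d_c`,
#' and Poisson(`d_c * m_g`) capture given expression. The realised depth
#' multipliers are stored as per-cell metadata so that depth-stratified
#' diagnostics can be run on the simulation truth.
#'
#' The marginal detection probability (count >= 1) of gene `g` is
#' `p_g * E_d[1 - exp(-d * m_g)]`; with constant depth, detection events of
#' different genes are independent, while heterogeneous depth induces the
#' positive association that inflates observed coexpression above the
#' product of marginals.
#'
#' @param params an [sc_sim_params()] object.
#' @return A [count_matrix()] with depth metadata.
#' @examples
#' pars <- sc_sim_params(500, c("Otx2", "En2"), expr_prob = c(0.3, 0.2),
#'                       depth_sigma = 0, seed = 1)
#' sim <- simulate_sc_counts(pars)
#' detection_fractions(detect(sim))
#' @export
simulate_sc_counts <- function(params) {
  stopifnot(inherits(params, "sc_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_cells
  genes <- params$genes
  d <- if (params$depth_sigma > 0)
    rlnorm(n, meanlog = 0, sdlog = params$depth_sigma) else rep(1, n)
  counts <- matrix(0L, nrow = length(genes), ncol = n,
                   dimnames = list(genes, sprintf("cell%05d", seq_len(n))))
  for (g in seq_along(genes)) {
    on <- rbinom(n, 1L, params$expr_prob[g]) == 1L
    if (any(on))
      counts[g, on] <- rpois(sum(on), d[on] * params$mean_capture[g])
  }
  count_matrix(counts, depth = d)
}

#' Specification of a planar migration field for track simulation
#'
#' Describes labelled cell groups moving in the embryo plane under a
#' (possibly position-dependent) velocity field, observed at a fixed frame
#' interval with isotropic Gaussian positional noise. The axis convention
#' follows the embryo: `+y` is posterior, `+x` the embryo's right, so a
#' posteriorly migrating spinal-cord precursor group has positive `vy`.
#'
#' The default groups emulate the two epiblast flows seen after midline
#' convergence: spinal-cord (`SC`) precursors drifting posteriorly at
#' 138 um/h and brain precursors (`brain`) drifting anteriorly at 60 um/h.
#'
#' @param groups named list; each element is a list with `velocity` (either
#'   a length-2 numeric um/h vector or a `function(x, y)` returning one),
#'   `n_cells`, and `origin` (list with `center` length-2 and `spread` sd um
#'   of initial positions).
#' @param frame_interval_min minutes between frames (default 10).
#' @param n_frames number of frames (>= 3; velocity estimation needs three
#'   consecutive frames).
#' @param noise_sd positional noise standard deviation per coordinate, um.
#' @param seed optional integer seed.
#' @return A list of class `field_spec`.
#' @export
field_spec <- function(groups = NULL, frame_interval_min = 10,
                       n_frames = 12, noise_sd = 5, seed = NULL) {
  if (frame_interval_min <= 0) stop("frame_interval_min must be positive")
  if (n_frames < 3L)
    stop("n_frames must be >= 3: velocity estimation needs three consecutive frames")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(groups)) {
    groups <- list(
      SC    = list(velocity = c(0, 138), n_cells = 50,
                   origin = list(center = c(0, 300), spread = 150)),
      brain = list(velocity = c(0, -60), n_cells = 50,
                   origin = list(center = c(0, -300), spread = 150)))
  }
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  for (g in groups) {
    if (!is.function(g$velocity) && length(g$velocity) != 2L)
      stop("group velocity must be a length-2 vector or function(x, y)")
    if (is.null(g$n_cells) || g$n_cells < 1L) stop("each group needs n_cells >= 1")
  }
  structure(list(groups = groups, frame_interval_min = frame_interval_min,
                 n_frames = as.integer(n_frames), noise_sd = noise_sd,
                 seed = seed),
            class = "field_spec")
}

#' Simulate labelled cell trajectories under a planar velocity field
#'
#' Each cell starts at a Gaussian-scattered origin and is advanced one frame
#' at a time: true displacement per frame is `velocity(position) *
#' frame_interval`, and the *recorded* position adds isotropic Gaussian
#' noise to the true position. One row per cell per frame is returned.
#'
#' @param spec a [field_spec()].
#' @return A `data.frame` (the track table) with columns `cell_id`, `group`,
#'   `frame`, `t_min`, `x_um`, `y_um`.
#' @examples
#' tr <- simulate_tracks(field_spec(noise_sd = 0, seed = 1))
#' head(tr)
#' @export
simulate_tracks <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  dt_h <- spec$frame_interval_min / 60
  out <- list()
  cell_counter <- 0L
  for (gname in names(spec$groups)) {
    g <- spec$groups[[gname]]
    vel <- if (is.function(g$velocity)) g$velocity else {
      vfix <- g$velocity
      function(x, y) vfix
    }
    origin <- if (is.null(g$origin)) list(center = c(0, 0), spread = 100) else g$origin
    for (i in seq_len(g$n_cells)) {
      cell_counter <- cell_counter + 1L
      pos <- origin$center + rnorm(2, 0, origin$spread)
      xs <- numeric(spec$n_frames); ys <- numeric(spec$n_frames)
      for (f in seq_len(spec$n_frames)) {
        noisy <- pos + if (spec$noise_sd > 0) rnorm(2, 0, spec$noise_sd) else c(0, 0)
        xs[f] <- noisy[1]; ys[f] <- noisy[2]
        v <- vel(pos[1], pos[2])
        pos <- pos + v * dt_h
      }
      out[[cell_counter]] <- data.frame(
        cell_id = sprintf("%s_%03d", gname, i), group = gname,
        frame = seq_len(spec$n_frames) - 1L,
        t_min = (seq_len(spec$n_frames) - 1L) * spec$frame_interval_min,
        x_um = xs, y_um = ys, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Parameters for tiered bulk expression profiles
#'
#' Bulk microarray-style profiles are generated from a *code matrix* of tier
#' labels (`off` / `low` / `high`) per sample and gene: each tier has a mean
#' intensity, each sample is measured in `replicates` biological replicates,
#' and multiplicative log-normal noise with standard deviation `noise_sd`
#' perturbs each replicate measurement.
#'
#' @param code sample x gene character matrix with entries in
#'   `c("off", "low", "high")` and row/column names.
#' @param tier_means named numeric vector of intensities for the three tiers.
#' @param replicates biological replicates per sample (>= 2, matching
#'   duplicate-sample designs).
#' @param noise_sd multiplicative (log-scale) noise sd; 0 for noise-free.
#' @param seed optional integer seed.
#' @return A list of class `bulk_sim_params`.
#' @seealso [nsc_line_code()] for the bundled six-line code.
#' @export
bulk_sim_params <- function(code,
                            tier_means = c(off = 0, low = 0.2, high = 1),
                            replicates = 2, noise_sd = 0.1, seed = NULL) {
  if (is.null(dim(code)) || is.null(rownames(code)) || is.null(colnames(code)))
    stop("`code` must be a sample x gene matrix with dimnames")
  bad <- setdiff(unique(as.vector(code)), c("off", "low", "high"))
  if (length(bad))
    stop("unknown tier label(s): ", paste(bad, collapse = ", "))
  if (!all(c("off", "low", "high") %in% names(tier_means)))
    stop("tier_means must name off, low and high")
  if (replicates < 2) stop("replicates must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(code = code, tier_means = tier_means,
                 replicates = as.integer(replicates),
                 noise_sd = noise_sd, seed = seed),
            class = "bulk_sim_params")
}

#' Simulate a bulk expression table from a tier code
#'
#' @param params a [bulk_sim_params()] object.
#' @return genes x (sample_replicate) numeric matrix; columns are named
#'   `<sample>_<replicate>`.
#' @examples
#' code <- matrix(c("high", "off", "low", "high"), 2, 2,
#'                dimnames = list(c("s1", "s2"), c("Foxg1", "Hoxa5")))
#' simulate_bulk_profiles(bulk_sim_params(code, noise_sd = 0))
#' @export
simulate_bulk_profiles <- function(params) {
  stopifnot(inherits(params, "bulk_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  samples <- rownames(params$code)
  genes <- colnames(params$code)
  cols <- as.vector(t(outer(samples, seq_len(params$replicates),
                            function(s, r) paste0(s, "_", r))))
  out <- matrix(0, nrow = length(genes), ncol = length(cols),
                dimnames = list(genes, cols))
  for (s in samples) {
    mu <- params$tier_means[params$code[s, genes]]
    for (r in seq_len(params$replicates)) {
      v <- if (params$noise_sd > 0)
        mu * rlnorm(length(mu), -params$noise_sd^2 / 2, params$noise_sd)
      else mu
      out[, paste0(s, "_", r)] <- v
    }
  }
  out
}
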
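#' Gene model for nascent-transcript live imaging
#'
#' Represents the geometry of an MS2/PP7-tagged gene: the physical length from
#' the transcription start site to the point where the nascent transcript (and
#' its fluorescent signal) is released, the end coordinates of the stem-loop
#' (or probe) binding sequences, and the Pol II elongation rate. These
#' quantities determine how a single initiation event maps onto fluorescent
#' signal over time.
#'
#' Coordinates are 0-based base pairs from the TSS; `loop_ends_bp` are the
#' *end* positions of each loop sequence, so a transcript of length `l`
#' contributes loop `i` as soon as `l >= loop_ends_bp[i]`.
#'
#' @param gene_length_bp Physical gene length L_g in bp (TSS to signal
#'   release; any retention time at the site is folded into this length).
#' @param loop_ends_bp Strictly increasing vector of loop end positions (bp),
#'   all in (0, L_g].
#' @param elongation_rate Pol II elongation rate K_elo in kb/min.
#' @param name Optional construct name.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_length_bp, loop_ends_bp, elongation_rate,
                       name = "gene") {
  stopifnot(length(gene_length_bp) == 1, gene_length_bp > 0,
            length(elongation_rate) == 1, elongation_rate > 0,
            length(loop_ends_bp) >= 1)
  loop_ends_bp <- as.numeric(loop_ends_bp)
  if (is.unsorted(loop_ends_bp, strictly = TRUE))
    stop("loop_ends_bp must be strictly increasing")
  if (any(loop_ends_bp <= 0) || any(loop_ends_bp > gene_length_bp))
    stop("loop positions must lie in (0, gene_length_bp]")
  structure(list(name = name,
                 gene_length_bp = as.numeric(gene_length_bp),
                 loop_ends_bp = loop_ends_bp,
                 n_loops = length(loop_ends_bp),
                 elongation_rate = as.numeric(elongation_rate)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model '%s'> L_g = %g bp, %d loops (%g-%g bp), K_elo = %g kb/min\n",
              x$name, x$gene_length_bp, x$n_loops, min(x$loop_ends_bp),
              max(x$loop_ends_bp), x$elongation_rate))
  invisible(x)
}

#' Read a gene model from a JSON file
#'
#' Expected fields: `name`, `gene_length_bp`, `loop_ends_bp`,
#' `elongation_rate_kb_per_min`.
#' @param path Path to a JSON file.
#' @return A `gene_model`.
#' @export
read_gene_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  gene_model(j$gene_length_bp, j$loop_ends_bp, j$elongation_rate_kb_per_min,
             name = if (!is.null(j$name)) j$name else "gene")
}

#' Default synthetic hunchback-like MS2 construct
#'
#' A plausible stand-in for a gap-gene MS2 reporter: a 24-loop cassette in the
#' 5' region of a ~4.5 kb transcription unit. The exact per-construct loop
#' coordinates are not published, so this model is synthetic; its effective
#' length gives an elongation time of ~1.8 min at 1.8 kb/min, consistent with
#' the ~2 min signal persistence of the gap genes.
#'
#' @param elongation_rate K_elo in kb/min (default 1.8).
#' @return A `gene_model`.
#' @export
gene_model_hb_synthetic <- function(elongation_rate = 1.8) {
  gene_model(gene_length_bp = 4500,
             loop_ends_bp = 600 + 54 * seq_len(24),
             elongation_rate = elongation_rate,
             name = "hb-MS2-synthetic")
}

#' Fractional signal contribution of a nascent transcript
#'
#' A transcript of length `l` carries the loops whose end positions have been
#' transcribed, each contributing 1/m of the full signal:
#' s(l) = (1/m) * #\{i : l >= l_i\}. The step convention is right-continuous
#' (a transcript exactly at a loop end carries that loop).
#'
#' @param l Transcript length(s) in bp, in \[0, L_g\].
#' @param gm A `gene_model`.
#' @return Fraction(s) in \[0, 1\], piecewise constant and non-decreasing.
#' @export
signal_contribution <- function(l, gm) {
  stopifnot(inherits(gm, "gene_model"))
  if (any(l < 0 | l > gm$gene_length_bp))
    stop("transcript length out of range [0, gene_length_bp]")
  vapply(l, function(li) sum(li >= gm$loop_ends_bp), 0) / gm$n_loops
}

#' Effective gene length
#'
#' The integral of the signal contribution s(l) over the gene,
#' L_tilde = L_g - mean(l_i): the length of fully tagged transcript a gene
#' effectively behaves as, accounting for loop positions.
#'
#' @param gm A `gene_model`.
#' @return Effective length in bp.
#' @export
effective_length <- function(gm) {
  stopifnot(inherits(gm, "gene_model"))
  gm$gene_length_bp - mean(gm$loop_ends_bp)
}

#' Elongation time of the gene
#'
#' tau_elo = L_tilde / K_elo in minutes: the mean residence time of the
#' fluorescent signal of one transcript.
#' @param gm A `gene_model`.
#' @return Minutes.
#' @export
elongation_time <- function(gm) {
  effective_length(gm) / (gm$elongation_rate * 1000)
}

#' Build the discrete elongation kernel
#'
#' The kernel kappa(t) is the fractional fluorescent signal of a single
#' transcript a time t after its initiation: it rises as loops are
#' transcribed and drops to exactly 0 once Pol II reaches the end of the gene
#' at t = L_g / K_elo. Discretized at `dt_fine` seconds with
#' weights\[j\] = s(K_elo * t_j) for t_j = (j-1) * dt_fine < L_g/K_elo and
#' k = floor(L_g / (K_elo * dt_fine)) + 1 steps.
#'
#' @param gm A `gene_model`.
#' @param dt_fine Fine sampling interval in seconds (must not exceed the
#'   dwell time L_g/K_elo).
#' @return An object of class `elongation_kernel` with fields `weights`,
#'   `dt_fine`, `n_steps`.
#' @export
build_kernel <- function(gm, dt_fine = 1) {
  stopifnot(inherits(gm, "gene_model"), dt_fine > 0)
  v_bp_s <- gm$elongation_rate * 1000 / 60   # bp per second
  dwell_s <- gm$gene_length_bp / v_bp_s
  if (dt_fine > dwell_s)
    stop("dt_fine exceeds the kernel dwell time L_g/K_elo")
  k <- floor(gm$gene_length_bp / (v_bp_s * dt_fine)) + 1
  tj <- (seq_len(k) - 1) * dt_fine
  w <- ifelse(tj < dwell_s, signal_contribution(pmin(v_bp_s * tj, gm$gene_length_bp), gm), 0)
  structure(list(weights = w, dt_fine = dt_fine, n_steps = k,
                 dwell_s = dwell_s, gene = gm$name),
            class = "elongation_kernel")
}

#' Length-normalization coefficients for activity cumulants
#'
#' C_k = (1/L_g) * integral of s(l)^k over the gene
#'     = sum_i (i/m)^k (l_\{i+1\} - l_i) / L_g with l_\{m+1\} = L_g.
#' For k = 1, C_1 * L_g equals the effective length.
#'
#' @param gm A `gene_model`.
#' @param k_order Cumulant order k >= 1 (vectorized).
#' @return Coefficient(s) C_k in \[0, 1\].
#' @export
cumulant_coefficients <- function(gm, k_order) {
  stopifnot(inherits(gm, "gene_model"), all(k_order >= 1))
  m <- gm$n_loops
  gaps <- diff(c(gm$loop_ends_bp, gm$gene_length_bp))
  vapply(k_order, function(k)
    sum((seq_len(m) / m)^k * gaps) / gm$gene_length_bp, 0)
}

#' Minimal interval between initiation events and the maximal rate
#'
#' The Pol II footprint f sets a refractory period below which two successive
#' initiations cannot occur. With `n_copies` unresolved gene copies sharing
#' one fine grid the minimal interval is f / (n_copies * K_elo); its inverse
#' is the maximal physically possible initiation rate.
#'
#' @param footprint_bp Pol II footprint in bp (conservative default 60).
#' @param k_elo Elongation rate in kb/min.
#' @param n_copies Number of unresolved gene copies (default 2 sister
#'   chromatids).
#' @return List with `dt_fine_s` (seconds) and `r_max` (mRNA/min).
#' @export
min_initiation_interval <- function(footprint_bp = 60, k_elo = 1.8, n_copies = 2) {
  dt_s <- footprint_bp / (n_copies * k_elo * 1000 / 60)
  list(dt_fine_s = dt_s, r_max = 60 / dt_s)
}
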
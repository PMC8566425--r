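# Synthetic flow-cytometry events and rectangular gating with ambiguity
# bands. Events carry intensities for CD45, CD3, CD19, CD14 and the 7-AAD
# viability dye; gating excludes dead cells, requires a minimum number of
# viable events, gates CD45+ leukocytes first, and classifies subsets within
# CD45+, dropping events inside any ambiguity band so subset percentages
# need not sum to 100.

FLOW_CHANNELS <- c("CD45", "CD3", "CD19", "CD14", "AAD7")

#' Flow event generator profile
#'
#' @param n_events total events.
#' @param viable_fraction fraction of events that are 7-AAD-negative.
#' @param cd45_fraction CD45+ fraction of viable mononuclear events
#'   (default 0.11, the reported filtrate leukocyte fraction).
#' @param subset_fractions named fractions of CD45+ events for CD3 (T),
#'   CD19 (B), CD14 (monocyte/macrophage).
#' @param ambiguous_fraction CD45+ events rendered inside a gate ambiguity
#'   band (excluded by gating).
#' @param neg_meanlog,pos_meanlog log-intensity of negative/positive
#'   populations.
#' @param sdlog log-sd of both populations.
#' @param seed integer seed.
#' @return object of class `flow_profile`.
#' @export
flow_profile <- function(n_events = 50000L, viable_fraction = 0.9,
                         cd45_fraction = 0.11,
                         subset_fractions = c(CD3 = 0.45, CD19 = 0.08,
                                              CD14 = 0.25),
                         ambiguous_fraction = 0.07,
                         neg_meanlog = log(80), pos_meanlog = log(5000),
                         sdlog = 0.35, seed = 1L) {
  if (n_events < 1L) stop("n_events must be >= 1")
  for (f in c(viable_fraction, cd45_fraction, subset_fractions,
              ambiguous_fraction))
    stopifnot_scalar(f, "fraction", 0, 1)
  if (sum(subset_fractions) + ambiguous_fraction > 1)
    stop("subset fractions plus ambiguous fraction exceed 1")
  stopifnot(setequal(names(subset_fractions), c("CD3", "CD19", "CD14")))
  structure(list(n_events = as.integer(n_events),
                 viable_fraction = viable_fraction,
                 cd45_fraction = cd45_fraction,
                 subset_fractions = subset_fractions,
                 ambiguous_fraction = ambiguous_fraction,
                 neg_meanlog = neg_meanlog, pos_meanlog = pos_meanlog,
                 sdlog = sdlog, seed = as.integer(seed)),
            class = "flow_profile")
}

#' Default gate configuration
#'
#' Per-channel positive threshold with a symmetric ambiguity band on the
#' log scale; events inside a band are excluded as ambiguously positive.
#'
#' @param threshold positive/negative boundary intensity.
#' @param band_factor band is `[threshold / band_factor, threshold *
#'   band_factor]`.
#' @param min_viable_events samples with fewer viable events error out.
#' @return object of class `gate_config`.
#' @export
gate_config <- function(threshold = 700, band_factor = 1.6,
                        min_viable_events = 10000L) {
  structure(list(threshold = threshold, band_factor = band_factor,
                 min_viable_events = as.integer(min_viable_events)),
            class = "gate_config")
}

#' Generate synthetic flow-cytometry events
#'
#' Events are a labeled mixture: dead (7-AAD+), CD45- (stromal/epithelial/
#' endothelial), and CD45+ subsets (T, B, monocyte, ambiguous, other
#' leukocyte), with log-normal channel intensities. Truth labels are kept.
#'
#' @param profile a [flow_profile()].
#' @param sample_id,donor_id,source copied into the table.
#' @return data.frame: channel intensities, `truth` label, identifiers.
#' @export
generate_flow_events <- function(profile, sample_id = "S1", donor_id = "D1",
                                 source = c("filtrate", "PBMC")) {
  stopifnot(inherits(profile, "flow_profile"))
  source <- match.arg(source)
  with_seed(profile$seed, {
    n <- profile$n_events
    dead <- stats::runif(n) >= profile$viable_fraction
    cd45p <- !dead & stats::runif(n) < profile$cd45_fraction
    sf <- profile$subset_fractions
    probs <- c(T = unname(sf["CD3"]), B = unname(sf["CD19"]),
               mono = unname(sf["CD14"]), ambiguous = profile$ambiguous_fraction)
    probs <- c(probs, other = max(0, 1 - sum(probs)))
    subset <- rep("none", n)
    subset[cd45p] <- sample(names(probs), sum(cd45p), TRUE, prob = probs)
    truth <- ifelse(dead, "dead", ifelse(!cd45p, "CD45neg", subset))

    rpos <- function(k) stats::rlnorm(k, profile$pos_meanlog, profile$sdlog)
    rneg <- function(k) stats::rlnorm(k, profile$neg_meanlog, profile$sdlog)
    ev <- data.frame(CD45 = rneg(n), CD3 = rneg(n), CD19 = rneg(n),
                     CD14 = rneg(n), AAD7 = rneg(n))
    ev$AAD7[dead] <- rpos(sum(dead))
    ev$CD45[cd45p] <- rpos(sum(cd45p))
    ev$CD3[truth == "T"] <- rpos(sum(truth == "T"))
    ev$CD19[truth == "B"] <- rpos(sum(truth == "B"))
    ev$CD14[truth == "mono"] <- rpos(sum(truth == "mono"))
    # ambiguous events sit inside the default band of one subset channel
    amb <- which(truth == "ambiguous")
    if (length(amb)) {
      chan <- sample(c("CD3", "CD19", "CD14"), length(amb), TRUE)
      gc <- gate_config()
      for (ch in c("CD3", "CD19", "CD14")) {
        sel <- amb[chan == ch]
        ev[[ch]][sel] <- stats::runif(length(sel),
                                      gc$threshold / gc$band_factor,
                                      gc$threshold * gc$band_factor)
      }
    }
    ev$truth <- truth
    ev$sample_id <- sample_id; ev$donor_id <- donor_id; ev$source <- source
    ev
  })
}

#' Exclude dead (7-AAD-positive) events
#'
#' @param events flow event table.
#' @param config a [gate_config()].
#' @return viable subset of `events`; errors with "insufficient events" when
#'   fewer than `config$min_viable_events` survive (the sample-inclusion
#'   rule).
#' @export
gate_viable <- function(events, config = gate_config()) {
  if (!"AAD7" %in% names(events)) stop("viability channel AAD7 missing")
  viable <- events[events$AAD7 <= config$threshold, , drop = FALSE]
  if (nrow(viable) < config$min_viable_events)
    stop(sprintf("insufficient events: %d viable < %d required",
                 nrow(viable), config$min_viable_events))
  viable
}

in_band <- function(x, config) {
  x > config$threshold / config$band_factor &
  x < config$threshold * config$band_factor
}

#' Gate leukocyte subsets
#'
#' CD45+ is gated first (of viable events outside the CD45 ambiguity band);
#' T (CD3+), B (CD19+) and monocyte/macrophage (CD14+) percentages are
#' computed within CD45+, excluding events inside any subset ambiguity band,
#' so the three percentages can sum to less than 100.
#'
#' @param viable_events output of [gate_viable()].
#' @param config a [gate_config()].
#' @return list: `cd45_pct` (of viable), `subset_pct` (named: T, B, mono, as
#'   % of CD45+), `n_viable`, `n_cd45`, `flag` (character, `"ok"` or
#'   `"no_cd45_events"`).
#' @export
gate_subsets <- function(viable_events, config = gate_config()) {
  ev <- viable_events
  cd45_eval <- ev[!in_band(ev$CD45, config), , drop = FALSE]
  cd45p <- cd45_eval[cd45_eval$CD45 > config$threshold, , drop = FALSE]
  cd45_pct <- 100 * nrow(cd45p) / nrow(cd45_eval)
  if (nrow(cd45p) == 0L)
    return(list(cd45_pct = cd45_pct, subset_pct = c(T = NA_real_,
                B = NA_real_, mono = NA_real_), n_viable = nrow(ev),
                n_cd45 = 0L, flag = "no_cd45_events"))
  amb <- in_band(cd45p$CD3, config) | in_band(cd45p$CD19, config) |
         in_band(cd45p$CD14, config)
  kept <- cd45p[!amb, , drop = FALSE]
  subset_pct <- c(
    T = 100 * sum(kept$CD3 > config$threshold) / nrow(cd45p),
    B = 100 * sum(kept$CD19 > config$threshold) / nrow(cd45p),
    mono = 100 * sum(kept$CD14 > config$threshold) / nrow(cd45p))
  list(cd45_pct = cd45_pct, subset_pct = subset_pct,
       n_viable = nrow(ev), n_cd45 = nrow(cd45p), flag = "ok")
}

#' Pearson correlation of immune proportions in matched blood and tissue
#'
#' @param paired data.frame with columns `blood` and `tissue` (one row per
#'   donor, one cell type at a time).
#' @return `stat_result` with `r` and two-sided p.
#' @export
blood_tissue_correlation <- function(paired) {
  stopifnot(all(c("blood", "tissue") %in% names(paired)))
  if (nrow(paired) < 3L) stop("need at least 3 donor-matched pairs")
  if (stats::var(paired$blood) == 0 || stats::var(paired$tissue) == 0)
    stop("zero variance in blood or tissue proportions")
  ct <- stats::cor.test(paired$blood, paired$tissue)
  new_stat_result("Pearson correlation (blood vs tissue)",
                  statistic = unname(ct$statistic), p_value = ct$p.value,
                  r = unname(ct$estimate), n = nrow(paired))
}
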
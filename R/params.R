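#' Alignment scoring scheme
#'
#' BWA-MEM-like defaults: the source pipeline publishes no scoring
#' constants, so these are stated here and overridable everywhere.
#' `unclipped_bonus` rewards alignments that consume the whole read,
#' discouraging spurious end clips.
#'
#' @param match per-base match score (> 0)
#' @param mismatch per-base mismatch penalty (>= 0, applied as negative)
#' @param gap_open gap opening penalty
#' @param gap_extend per-base gap extension penalty
#' @param unclipped_bonus score bonus for a clip-free alignment
#' @return object of class `scoring_scheme`
#' @export
scoring_scheme <- function(match = 2L, mismatch = 3L, gap_open = 5L,
                           gap_extend = 1L, unclipped_bonus = 5L) {
  stopifnot(match > 0, mismatch >= 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 unclipped_bonus = as.integer(unclipped_bonus)),
            class = "scoring_scheme")
}

#' Mapper configuration
#'
#' Gathers the scoring scheme, gapped-alignment triggers, the paired-end
#' insert model, rescue-scan settings, and the MAPQ constants.
#'
#' The gapless aligner hands a candidate to Smith-Waterman when its score
#' falls below `trigger_fraction` of the perfect score or an end clip
#' exceeds `clip_trigger` nt.  A proper pair must lie within
#' `insert_window` standard deviations of the insert mean; the insert
#' model is fitted from the first `insert_fit_n` proper FR pairs aligned
#' without rescue (falling back to `insert_mean`/`insert_sd`).  MAPQ is
#' `clamp(round(mapq_coeff/L * (S1 - S2)) - mapq_beta*log2(1 + N2), 0,
#' 60)` where `N2` counts candidates scoring within `near_window` of the
#' second best; a read with no second-best candidate gets the cap.
#'
#' @param scheme a [scoring_scheme()]
#' @param trigger_fraction gapless score fraction below which gapped
#'   alignment runs
#' @param clip_trigger clip length (nt) above which gapped alignment runs
#' @param sw_band reference window padding (nt) around a chain diagonal
#' @param insert_mean,insert_sd configured fallback insert model (nt)
#' @param insert_window proper-pair window, in multiples of insert_sd
#' @param fit_insert fit the insert model from the data?
#' @param insert_fit_n pairs used for the fit
#' @param rescue_kmer mate k-mer length for the rescue scan (nt)
#' @param rescue_hamming maximum Hamming distance for a rescue k-mer match
#' @param mapq_coeff MAPQ proportionality numerator (divided by read length)
#' @param mapq_beta weight of the near-second-best correction
#' @param near_window score window counted as "very close to second best"
#' @param cover_fraction read coverage below which supplementary
#'   alignments are emitted
#' @param pair_pen_coeff pairing penalty per sd of insert deviation
#' @param pair_pen_cap cap on the pairing penalty (also the improper-pair
#'   penalty)
#' @param min_score minimum alignment score to report a mapping
#' @param max_chains seed chains retained per read after filtering
#' @return object of class `map_params`
#' @export
map_params <- function(scheme = scoring_scheme(), trigger_fraction = 0.9,
                       clip_trigger = 5L, sw_band = 50L,
                       insert_mean = 350, insert_sd = 50,
                       insert_window = 4, fit_insert = TRUE,
                       insert_fit_n = 10000L, rescue_kmer = 24L,
                       rescue_hamming = 3L, mapq_coeff = 6.0,
                       mapq_beta = 2.0, near_window = 2L,
                       cover_fraction = 0.8, pair_pen_coeff = 1.0,
                       pair_pen_cap = 30L, min_score = 30L,
                       max_chains = 16L) {
  structure(list(match = scheme$match, mismatch = scheme$mismatch,
                 gap_open = scheme$gap_open, gap_extend = scheme$gap_extend,
                 unclipped_bonus = scheme$unclipped_bonus,
                 trigger_fraction = trigger_fraction,
                 clip_trigger = as.integer(clip_trigger),
                 sw_band = as.integer(sw_band),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 insert_window = insert_window, fit_insert = fit_insert,
                 insert_fit_n = as.integer(insert_fit_n),
                 rescue_kmer = as.integer(rescue_kmer),
                 rescue_hamming = as.integer(rescue_hamming),
                 mapq_coeff = mapq_coeff, mapq_beta = mapq_beta,
                 near_window = as.integer(near_window),
                 cover_fraction = cover_fraction,
                 pair_pen_coeff = pair_pen_coeff,
                 pair_pen_cap = as.integer(pair_pen_cap),
                 min_score = as.integer(min_score),
                 max_chains = as.integer(max_chains)),
            class = "map_params")
}

#' Variant-caller configuration
#'
#' `min_depth` and `min_mapq` define callable columns; active regions are
#' maximal runs of columns whose non-reference evidence fraction reaches
#' `evidence_threshold`, padded by `base_pad` nt (`indel_pad` when the run
#' carries indel evidence).  Local assembly tries k-mer sizes from
#' `k_schedule` until the graph is non-degenerate, pruning non-reference
#' edges observed fewer than `prune_weight` times, and caps candidate
#' haplotypes at `max_haplotypes`.  The pair-HMM takes its gap-open
#' probability from a PCR error model keyed to homopolymer run length,
#' `10^-(pcr_scale - pcr_slope * min(run, pcr_max_run))`, with constant
#' gap extension `hmm_gap_ext`.  Non-reference diplotypes share a
#' heterozygosity prior `theta`.  Insertions/deletions longer than
#' `max_event_len` nt are discarded as assembly artifacts.
#'
#' @param min_depth minimum aligned depth for a callable column
#' @param min_mapq minimum MAPQ for a read to contribute
#' @param evidence_threshold non-reference evidence fraction that triggers
#'   an active region
#' @param base_pad padding (nt) around an active run
#' @param indel_pad padding (nt) when the run has indel evidence
#' @param k_schedule k-mer sizes tried in order by the assembler
#' @param prune_weight minimum observations for a non-reference edge
#' @param max_haplotypes candidate haplotype cap per region
#' @param theta heterozygosity prior shared by non-reference diplotypes
#' @param hmm_gap_ext pair-HMM gap extension probability
#' @param pcr_scale,pcr_slope,pcr_max_run PCR error model constants
#' @param max_event_len cap (nt) on insertion/deletion length
#' @param max_region_reads reads used per region (downsampled above this)
#' @return object of class `caller_params`
#' @export
caller_params <- function(min_depth = 4L, min_mapq = 20L,
                          evidence_threshold = 0.15, base_pad = 50L,
                          indel_pad = 150L,
                          k_schedule = c(10L, 25L, 40L, 55L),
                          prune_weight = 2L, max_haplotypes = 128L,
                          theta = 0.001, hmm_gap_ext = 0.1,
                          pcr_scale = 4, pcr_slope = 0.5, pcr_max_run = 6L,
                          max_event_len = 470L, max_region_reads = 200L) {
  structure(list(min_depth = as.integer(min_depth),
                 min_mapq = as.integer(min_mapq),
                 evidence_threshold = evidence_threshold,
                 base_pad = as.integer(base_pad),
                 indel_pad = as.integer(indel_pad),
                 k_schedule = as.integer(k_schedule),
                 prune_weight = as.integer(prune_weight),
                 max_haplotypes = as.integer(max_haplotypes),
                 theta = theta, hmm_gap_ext = hmm_gap_ext,
                 pcr_scale = pcr_scale, pcr_slope = pcr_slope,
                 pcr_max_run = as.integer(pcr_max_run),
                 max_event_len = as.integer(max_event_len),
                 max_region_reads = as.integer(max_region_reads)),
            class = "caller_params")
}
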
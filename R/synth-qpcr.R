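#' Configuration for simulated qPCR plates
#'
#' Generates Ct tables with the structure of a methylation-sensitive
#' restriction enzyme (MSRE) qPCR experiment and/or an RT-qPCR expression
#' assay. The MSRE model: AciI digestion destroys the unmethylated fraction
#' of the MSRE amplicon only, so the amplifiable template is `f` (the
#' effective methylated fraction) times the input and the MSRE Ct is delayed
#' by `-log_E(f)` cycles relative to the undigested control amplicon. The
#' all-or-nothing single-fraction model is the default; a per-site model
#' (amplifiable fraction `p^k` for `k` sites with per-site methylation
#' probability `p`) is available via `per_site_k`.
#'
#' @param conditions tibble with columns `condition`,
#'   `methylated_fraction` (in `[0,1]`) and `expression_fold` (> 0), one row
#'   per condition; see [qpcr_preset()] for ready-made tables.
#' @param ct_baseline mean control-amplicon Ct (cycles).
#' @param efficiency amplification factor per cycle, in `(1, 2]`.
#' @param technical_sd per-well Gaussian Ct noise sd (cycles).
#' @param n_technical technical replicates per well.
#' @param n_biological independent biological repeats.
#' @param ref_gene_ct mean reference-gene Ct for the expression assay.
#' @param expr_target_ct mean target Ct at expression fold 1.
#' @param per_site_k if not `NULL`, interpret `methylated_fraction` as the
#'   per-site methylation probability and protect the amplicon with
#'   probability `p^k` across `k` enzyme sites.
#' @param seed integer seed.
#' @return A validated `qpcr_sim_config` list.
#' @export
qpcr_sim_config <- function(conditions, ct_baseline = 24, efficiency = 2.0,
                            technical_sd = 0.2, n_technical = 3,
                            n_biological = 3, ref_gene_ct = 18,
                            expr_target_ct = 28, per_site_k = NULL,
                            seed = NULL) {
  stopifnot(is.data.frame(conditions),
            all(c("condition", "methylated_fraction") %in% names(conditions)))
  if (!"expression_fold" %in% names(conditions)) conditions$expression_fold <- 1
  stopifnot(all(conditions$methylated_fraction >= 0),
            all(conditions$methylated_fraction <= 1),
            all(conditions$expression_fold >= 0),
            efficiency > 1, efficiency <= 2,
            technical_sd >= 0, n_technical >= 1, n_biological >= 1)
  structure(list(conditions = tibble::as_tibble(conditions),
                 ct_baseline = ct_baseline, efficiency = efficiency,
                 technical_sd = technical_sd,
                 n_technical = as.integer(n_technical),
                 n_biological = as.integer(n_biological),
                 ref_gene_ct = ref_gene_ct, expr_target_ct = expr_target_ct,
                 per_site_k = per_site_k, seed = seed),
            class = c("qpcr_sim_config", "list"))
}

#' Simulate an MSRE-qPCR / RT-qPCR Ct plate
#'
#' One row per well. Roles follow the assay design: `msre_control` is the
#' undigested-input normalizer amplicon (no AciI sites), `msre_target` the
#' AciI-site-containing amplicon whose Ct is delayed by `-log_E(f)` cycles;
#' `expr_reference` / `expr_target` are the reference-gene and
#' alpha-satellite transcript wells, the target offset by
#' `-log_E(expression_fold)`. A methylated fraction of exactly 0 leaves no
#' amplifiable MSRE template: the well Ct is the `"undetermined"` sentinel
#' (`ct = NA`, `undetermined = TRUE`).
#'
#' @param cfg a [qpcr_sim_config()].
#' @param assay which well families to generate.
#' @return A tibble with columns `sample_id`, `condition`,
#'   `biological_repeat`, `primer_role`, `technical_replicate`, `ct`,
#'   `undetermined`.
#' @export
#' @examples
#' cfg <- qpcr_sim_config(qpcr_preset("mcf10a_aza")$conditions, seed = 1)
#' simulate_qpcr_plate(cfg)
simulate_qpcr_plate <- function(cfg, assay = c("msre", "expression", "both")) {
  stopifnot(inherits(cfg, "qpcr_sim_config"))
  assay <- match.arg(assay)
  logE <- function(x) log(x) / log(cfg$efficiency)
  with_seed_local(cfg$seed, {
    grid <- tidyr::expand_grid(
      condition = cfg$conditions$condition,
      biological_repeat = seq_len(cfg$n_biological),
      technical_replicate = seq_len(cfg$n_technical)
    )
    grid <- dplyr::left_join(grid, cfg$conditions, by = "condition")
    rows <- list()
    noise <- function(n) stats::rnorm(n, 0, cfg$technical_sd)
    # both amplicons of a well pair are measured on the same DNA/RNA input,
    # so the digested/target Ct is anchored to that sample's realized
    # normalizer Ct plus its own well noise
    if (assay %in% c("msre", "both")) {
      f <- grid$methylated_fraction
      if (!is.null(cfg$per_site_k)) f <- f^cfg$per_site_k
      ctrl_ct <- cfg$ct_baseline + noise(nrow(grid))
      ctrl <- dplyr::mutate(grid, primer_role = "msre_control",
                            ct = ctrl_ct, undetermined = FALSE)
      tgt <- dplyr::mutate(grid, primer_role = "msre_target",
                           ct = ifelse(f > 0,
                                       ctrl_ct - logE(f) + noise(nrow(grid)),
                                       NA_real_),
                           undetermined = f <= 0)
      rows <- c(rows, list(ctrl, tgt))
    }
    if (assay %in% c("expression", "both")) {
      ref_ct <- cfg$ref_gene_ct + noise(nrow(grid))
      ref <- dplyr::mutate(grid, primer_role = "expr_reference",
                           ct = ref_ct, undetermined = FALSE)
      offset <- cfg$expr_target_ct - cfg$ref_gene_ct
      tgt <- dplyr::mutate(grid, primer_role = "expr_target",
                           ct = ifelse(grid$expression_fold > 0,
                                       ref_ct + offset -
                                         logE(pmax(grid$expression_fold, .Machine$double.xmin)) +
                                         noise(nrow(grid)),
                                       NA_real_),
                           undetermined = grid$expression_fold <= 0)
      rows <- c(rows, list(ref, tgt))
    }
    out <- dplyr::bind_rows(rows)
    out$sample_id <- paste(out$condition, out$biological_repeat, sep = "_r")
    out[, c("sample_id", "condition", "biological_repeat", "primer_role",
            "technical_replicate", "ct", "undetermined")]
  })
}
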
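#' Count restriction-enzyme recognition sites in a DNA sequence
#'
#' AciI recognizes `CCGC`, a non-palindromic motif, so a site on either
#' strand of a double-stranded template is cut: with
#' `count_both_strands = TRUE` both the motif and its reverse complement
#' (`GCGG` for AciI) are counted on the given strand. Overlapping matches
#' are counted by default.
#'
#' @param sequence a single DNA string (uppercase `ACGTN`).
#' @param motif recognition motif (default `"CCGC"`, AciI).
#' @param count_both_strands also count the reverse-complement motif.
#' @param allow_overlap count overlapping occurrences (default `TRUE`);
#'   otherwise matches are consumed greedily left to right.
#' @return Integer site count.
#' @export
#' @examples
#' count_enzyme_sites("AACCGCTT")            # 1
#' count_enzyme_sites("AAGCGGTT")            # 1 (site on the other strand)
count_enzyme_sites <- function(sequence, motif = "CCGC",
                               count_both_strands = TRUE,
                               allow_overlap = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  bad <- which(!strsplit(sequence, "")[[1]] %in% c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("invalid DNA characters at position(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  subject <- Biostrings::DNAString(sequence)
  motifs <- motif
  if (count_both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    if (rc != motif) motifs <- c(motif, rc)
  }
  count_one <- function(m) {
    if (allow_overlap) {
      Biostrings::countPattern(m, subject)
    } else {
      # greedy non-overlapping scan
      hits <- Biostrings::start(Biostrings::matchPattern(m, subject))
      n <- 0L; last_end <- 0L
      for (s in hits) {
        if (s > last_end) { n <- n + 1L; last_end <- s + nchar(m) - 1L }
      }
      n
    }
  }
  sum(vapply(motifs, count_one, integer(1)))
}

#' Amplicon specification for MSRE-qPCR validation
#'
#' @param name amplicon name.
#' @param sequence amplicon DNA sequence (given strand).
#' @param forward_primer,reverse_primer primer sequences; the forward
#'   primer must occur on the given strand, the reverse primer as its
#'   reverse complement, in amplifying orientation.
#' @param role `"msre_target"` (must contain >= 1 enzyme site) or
#'   `"msre_control"` (must contain none; used for input normalization).
#' @param enzyme_motif MSRE recognition motif (default AciI `CCGC`).
#' @param fragmentation_motif pre-fragmentation enzyme motif that must not
#'   cut inside the amplicon (default XbaI `TCTAGA`).
#' @return An `amplicon_spec` list.
#' @export
amplicon_spec <- function(name, sequence, forward_primer, reverse_primer,
                          role = c("msre_target", "msre_control"),
                          enzyme_motif = "CCGC",
                          fragmentation_motif = "TCTAGA") {
  role <- match.arg(role)
  structure(list(name = name, sequence = toupper(sequence),
                 forward_primer = toupper(forward_primer),
                 reverse_primer = toupper(reverse_primer), role = role,
                 enzyme_motif = enzyme_motif,
                 fragmentation_motif = fragmentation_motif),
            class = c("amplicon_spec", "list"))
}

#' Validate an amplicon against its assay role
#'
#' Checks primer presence and orientation, amplicon length, the
#' role-dependent enzyme-site requirement (an MSRE target amplicon must
#' contain at least one site; the control amplicon none) and that the
#' pre-fragmentation enzyme does not cut inside the amplicon.
#'
#' @param spec an [amplicon_spec()].
#' @return Tibble with one row per check: `check`, `pass`, `detail`; the
#'   attribute `"valid"` is `TRUE` when every check passes.
#' @export
validate_amplicon <- function(spec) {
  stopifnot(inherits(spec, "amplicon_spec"))
  seq <- spec$sequence
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  fwd_pos <- regexpr(spec$forward_primer, seq, fixed = TRUE)
  rev_rc <- rc(spec$reverse_primer)
  rev_pos <- regexpr(rev_rc, seq, fixed = TRUE)
  n_sites <- count_enzyme_sites(seq, spec$enzyme_motif)
  n_frag <- count_enzyme_sites(seq, spec$fragmentation_motif)
  site_ok <- if (spec$role == "msre_target") n_sites >= 1 else n_sites == 0
  checks <- tibble::tibble(
    check = c("forward_primer_present", "reverse_primer_present",
              "primer_orientation", "enzyme_sites_match_role",
              "no_internal_fragmentation_site"),
    pass = c(fwd_pos > 0,
             rev_pos > 0,
             fwd_pos > 0 && rev_pos > 0 &&
               fwd_pos < rev_pos + nchar(rev_rc) - 1,
             site_ok,
             n_frag == 0),
    detail = c(
      if (fwd_pos > 0) paste0("found at ", fwd_pos) else
        paste0("forward primer ", spec$forward_primer, " absent"),
      if (rev_pos > 0) paste0("reverse complement found at ", rev_pos) else
        paste0("reverse primer ", spec$reverse_primer,
               " absent (as reverse complement)"),
      paste0("amplicon length ", nchar(seq)),
      paste0(n_sites, " ", spec$enzyme_motif, " site(s); role ", spec$role,
             " requires ", if (spec$role == "msre_target") ">= 1" else "0"),
      paste0(n_frag, " ", spec$fragmentation_motif, " site(s) inside amplicon"))
  )
  attr(checks, "valid") <- all(checks$pass)
  attr(checks, "n_sites") <- n_sites
  checks
}

# technical replicates are averaged on the Ct scale before exponentiation
mean_ct_by_role <- function(ct_table, roles) {
  sub <- ct_table[ct_table$primer_role %in% roles, , drop = FALSE]
  und <- if ("undetermined" %in% names(sub)) sub$undetermined else is.na(sub$ct)
  sub$.und <- und
  dplyr::summarise(
    dplyr::group_by(sub, .data$condition, .data$biological_repeat,
                    .data$primer_role),
    mean_ct = mean(.data$ct[!.data$.und]),
    all_undetermined = all(.data$.und),
    .groups = "drop")
}

#' Relative methylation from an MSRE-qPCR Ct table
#'
#' Technical replicates are averaged on the Ct scale first (pinned
#' behaviour: averaging after exponentiation would give a different,
#' Jensen-biased estimate). Then per condition and biological repeat
#' `delta_ct = mean Ct(msre_target) - mean Ct(msre_control)` and
#' `relative_methylation = efficiency^-delta_ct`; the undigested control
#' amplicon serves as input normalizer. A fully undetermined MSRE target is
#' flagged `below_detection` with `relative_methylation = NA`; a missing
#' control amplicon is an error.
#'
#' @param ct_table tibble of Ct records (columns `condition`,
#'   `biological_repeat`, `primer_role`, `ct`, optional `undetermined`).
#' @param efficiency amplification factor per cycle (default 2).
#' @param reference_condition if given, adds `percent_of_reference`:
#'   100 x relative_methylation / mean relative_methylation of that
#'   condition.
#' @return Tibble of class `methylation_estimate` with `condition`,
#'   `biological_repeat`, `delta_ct`, `relative_methylation`,
#'   `below_detection` (and optionally `percent_of_reference`).
#' @export
#' @examples
#' plate <- simulate_qpcr_plate(
#'   qpcr_sim_config(qpcr_preset("mcf10a_aza")$conditions, seed = 1))
#' msre_relative_methylation(plate, reference_condition = "mock")
msre_relative_methylation <- function(ct_table, efficiency = 2.0,
                                      reference_condition = NULL) {
  stopifnot(efficiency > 1, efficiency <= 2)
  m <- mean_ct_by_role(ct_table, c("msre_target", "msre_control"))
  wide <- tidyr::pivot_wider(m, names_from = "primer_role",
                             values_from = c("mean_ct", "all_undetermined"))
  if (!"mean_ct_msre_control" %in% names(wide) ||
      any(is.na(wide$mean_ct_msre_control))) {
    stop("missing msre_control Ct for at least one (condition, repeat)")
  }
  if (!"mean_ct_msre_target" %in% names(wide)) {
    stop("no msre_target rows in the Ct table")
  }
  out <- tibble::tibble(
    condition = wide$condition,
    biological_repeat = wide$biological_repeat,
    delta_ct = wide$mean_ct_msre_target - wide$mean_ct_msre_control,
    below_detection = wide$all_undetermined_msre_target
  )
  out$relative_methylation <- ifelse(out$below_detection, NA_real_,
                                     efficiency^(-out$delta_ct))
  if (!is.null(reference_condition)) {
    if (!reference_condition %in% out$condition) {
      stop("reference_condition '", reference_condition, "' not in table")
    }
    ref <- mean(out$relative_methylation[out$condition == reference_condition],
                na.rm = TRUE)
    out$percent_of_reference <- 100 * out$relative_methylation / ref
  }
  class(out) <- c("methylation_estimate", class(out))
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per condition and biological repeat, `delta_ct = mean Ct(expr_target) -
#' mean Ct(expr_reference)` (technical replicates averaged on the Ct scale
#' first; the reference gene, e.g. RPLP0, normalizes input). The
#' `delta_delta_ct` subtracts the matching biological repeat of
#' `reference_condition` when that repeat exists, otherwise the reference
#' condition's mean `delta_ct`; `fold_change = efficiency^-delta_delta_ct`.
#'
#' @inheritParams msre_relative_methylation
#' @param reference_condition condition that defines fold change 1.
#' @return Tibble of class `expression_estimate` with `condition`,
#'   `biological_repeat`, `delta_ct`, `delta_delta_ct`, `fold_change`.
#' @export
ddct_expression <- function(ct_table, efficiency = 2.0, reference_condition) {
  stopifnot(efficiency > 1, efficiency <= 2)
  m <- mean_ct_by_role(ct_table, c("expr_target", "expr_reference"))
  wide <- tidyr::pivot_wider(m, names_from = "primer_role",
                             values_from = c("mean_ct", "all_undetermined"))
  for (col in c("mean_ct_expr_target", "mean_ct_expr_reference")) {
    if (!col %in% names(wide) || any(is.na(wide[[col]]))) {
      stop("missing ", sub("mean_ct_", "", col),
           " Ct for at least one (condition, repeat)")
    }
  }
  out <- tibble::tibble(
    condition = wide$condition,
    biological_repeat = wide$biological_repeat,
    delta_ct = wide$mean_ct_expr_target - wide$mean_ct_expr_reference
  )
  if (!reference_condition %in% out$condition) {
    stop("reference_condition '", reference_condition, "' not in table")
  }
  ref <- out[out$condition == reference_condition, ]
  ref_by_repeat <- stats::setNames(ref$delta_ct,
                                   as.character(ref$biological_repeat))
  ref_mean <- mean(ref$delta_ct)
  matched <- unname(ref_by_repeat[as.character(out$biological_repeat)])
  out$delta_delta_ct <- out$delta_ct - ifelse(is.na(matched), ref_mean, matched)
  out$fold_change <- efficiency^(-out$delta_delta_ct)
  class(out) <- c("expression_estimate", class(out))
  out
}
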
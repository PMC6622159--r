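# End-to-end orchestration: a run configuration, a contact-comparison stage
# and a coupling-evaluation stage, with deterministic text outputs.

#' Build a run configuration
#'
#' Collects everything the pipeline stages need: the structure, the coupling
#' source, the contact definitions to evaluate, and the cutoff regime.
#' Fixed-mode default cutoffs are 8 angstrom for CA, 7.6 for CB, 7.5 for the
#' side-chain center and 4.5 for the two minimum-atomic-distance methods;
#' matched mode instead matches every method's contact count to the CA
#' 8-angstrom definition.
#'
#' @param structure Path to a PDB file, PDB text, or a `protein_structure`.
#' @param chain Chain identifier (passed to [load_structure()]).
#' @param alignment Path to a FASTA/A2M alignment, or an `alignment` object;
#'   used to compute MI+APC couplings when no coupling matrix is given.
#' @param coupling_matrix Path to a plain-text L x L score matrix, or a
#'   `coupling_matrix` object.
#' @param methods Contact definitions to evaluate.
#' @param cutoff_mode `"matched"` (count-matched to CA 8 angstrom) or
#'   `"fixed"` (per-method cutoffs).
#' @param cutoffs Named fixed-mode cutoffs in angstrom.
#' @param min_sep Minimum chain separation (default 12).
#' @param k_rule Ranking depth as a fraction of L (default 0.5, i.e. top L/2).
#' @param seed Seed controlling any randomness in a run (logged in outputs).
#' @param output_dir Directory for report files; created if missing.
#' @param reweight If `TRUE` (default), MI+APC uses sequence weights at the
#'   0.8 identity threshold.
#' @return Object of class `run_config`.
#' @export
run_config <- function(structure, chain = NULL, alignment = NULL,
                       coupling_matrix = NULL,
                       methods = c("CA", "CB", "SC_CENTER", "MIN_ALL", "MIN_SC"),
                       cutoff_mode = c("matched", "fixed"),
                       cutoffs = c(CA = 8, CB = 7.6, SC_CENTER = 7.5,
                                   MIN_ALL = 4.5, MIN_SC = 4.5),
                       min_sep = 12, k_rule = 0.5, seed = 1,
                       output_dir = tempfile("eccontacts_run_"),
                       reweight = TRUE) {
  cutoff_mode <- match.arg(cutoff_mode)
  for (m in methods) .check_method(m)
  stopifnot(all(methods %in% names(cutoffs)) || cutoff_mode == "matched",
            min_sep >= 1, k_rule > 0, k_rule <= 1)
  structure(list(structure = structure, chain = chain, alignment = alignment,
                 coupling_matrix = coupling_matrix, methods = methods,
                 cutoff_mode = cutoff_mode, cutoffs = cutoffs,
                 min_sep = min_sep, k_rule = k_rule, seed = as.integer(seed),
                 output_dir = output_dir, reweight = reweight),
            class = "run_config")
}

.cfg_structure <- function(cfg) {
  if (inherits(cfg$structure, "protein_structure")) return(cfg$structure)
  load_structure(cfg$structure, cfg$chain)
}

.cfg_contact_maps <- function(cfg, s) {
  dms <- lapply(cfg$methods, function(m) distance_matrix(s, m))
  names(dms) <- cfg$methods
  maps <- list()
  eff <- stats::setNames(rep(NA_real_, length(cfg$methods)), cfg$methods)
  if (cfg$cutoff_mode == "matched") {
    dm_ca <- if ("CA" %in% cfg$methods) dms[["CA"]] else distance_matrix(s, "CA")
    n <- nrow(contacts_fixed(dm_ca, 8, cfg$min_sep)$pairs)
    if (n == 0L) stop("no CA 8-angstrom contacts; cannot match counts")
    for (m in cfg$methods) {
      if (m == "CA") {
        maps[[m]] <- contacts_fixed(dms[[m]], 8, cfg$min_sep)
        eff[m] <- 8
      } else {
        mc <- contacts_matched(dms[[m]], n, cfg$min_sep)
        maps[[m]] <- mc$contact_map
        eff[m] <- mc$effective_cutoff
      }
    }
  } else {
    for (m in cfg$methods) {
      maps[[m]] <- contacts_fixed(dms[[m]], cfg$cutoffs[[m]], cfg$min_sep)
      eff[m] <- cfg$cutoffs[[m]]
    }
  }
  list(dms = dms, maps = maps, effective_cutoffs = eff)
}

.write_header <- function(path, cfg, s) {
  cat(sprintf("# eccontacts run | seed %d | chain %s | L %d | min_sep %d | mode %s\n",
              cfg$seed, s$chain_id, s$L, cfg$min_sep, cfg$cutoff_mode),
      file = path)
}

#' Contact-map comparison stage
#'
#' Computes per-method distance matrices and contact maps, every pairwise
#' contact overlap (matched mode) or contact counts (fixed mode), and the
#' Spearman correlations between the methods' eligible-pair distances.
#' Writes one contact file per method plus a JSON report to
#' `cfg$output_dir`.
#'
#' @param cfg A `run_config`.
#' @return Object of class `contact_report`: list with `L`, `counts`,
#'   `effective_cutoffs`, `overlaps` (matrix or `NULL` in fixed mode),
#'   `spearman` (matrix), `maps`, and `output_dir`.
#' @export
run_contacts <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  s <- .cfg_structure(cfg)
  cc <- .cfg_contact_maps(cfg, s)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  nm <- cfg$methods
  counts <- vapply(cc$maps, function(m) nrow(m$pairs), 0L)
  spearman <- matrix(1, length(nm), length(nm), dimnames = list(nm, nm))
  overlaps <- if (cfg$cutoff_mode == "matched") {
    matrix(1, length(nm), length(nm), dimnames = list(nm, nm))
  } else NULL
  if (length(nm) > 1L) {
    for (a in seq_along(nm)[-length(nm)]) {
      for (b in (a + 1L):length(nm)) {
        rho <- distance_correlation(cc$dms[[a]], cc$dms[[b]], cfg$min_sep)
        spearman[a, b] <- rho
        spearman[b, a] <- rho
        if (!is.null(overlaps)) {
          ov <- overlap_fraction(cc$maps[[a]], cc$maps[[b]])
          overlaps[a, b] <- ov
          overlaps[b, a] <- ov
        }
      }
    }
  }
  for (m in nm) {
    write_contacts(cc$maps[[m]], file.path(cfg$output_dir,
                                           paste0("contacts_", m, ".txt")))
  }
  report <- list(L = s$L, counts = as.list(counts),
                 effective_cutoffs = as.list(round(cc$effective_cutoffs, 4)),
                 overlaps = if (!is.null(overlaps)) round(overlaps, 6),
                 spearman = round(spearman, 6),
                 seed = cfg$seed, min_sep = cfg$min_sep,
                 cutoff_mode = cfg$cutoff_mode)
  jsonlite::write_json(report, file.path(cfg$output_dir, "contact_report.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  structure(list(L = s$L, counts = counts,
                 effective_cutoffs = cc$effective_cutoffs,
                 overlaps = overlaps, spearman = spearman, maps = cc$maps,
                 structure = s, output_dir = cfg$output_dir),
            class = "contact_report")
}

#' @export
print.contact_report <- function(x, ...) {
  cat("contact_report: L =", x$L, "\n")
  cat("contacts:", paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  cat("effective cutoffs (A):",
      paste(names(x$effective_cutoffs), round(x$effective_cutoffs, 2),
            sep = "=", collapse = " "), "\n")
  if (!is.null(x$overlaps)) {
    cat("pairwise contact overlap:\n")
    print(round(x$overlaps, 3))
  }
  invisible(x)
}

.cfg_couplings <- function(cfg, s) {
  if (!is.null(cfg$coupling_matrix)) {
    cm <- if (inherits(cfg$coupling_matrix, "coupling_matrix")) {
      cfg$coupling_matrix
    } else {
      read_coupling_matrix(cfg$coupling_matrix)
    }
    if (cm$L != s$L) {
      stop("coupling matrix L = ", cm$L, " does not match structure L = ", s$L)
    }
    return(cm)
  }
  if (is.null(cfg$alignment)) stop("run_eval needs an alignment or a coupling matrix")
  aln <- if (inherits(cfg$alignment, "alignment")) cfg$alignment
         else read_alignment(cfg$alignment)
  aln <- filter_to_reference(aln)
  if (aln$n_cols != s$L) {
    stop("filtered alignment has ", aln$n_cols,
         " columns but structure L = ", s$L)
  }
  w <- if (cfg$reweight) sequence_weights(aln) else NULL
  mi_apc(aln, weights = w)
}

#' Coupling-evaluation stage
#'
#' Ranks couplings (from a supplied matrix or MI+APC on the alignment),
#' scores them against each configured contact definition (PPV at the
#' configured depth plus average precision), and summarises side-chain
#' orientations for all eligible pairs, each contact map, and the top
#' 0.25L / 0.5L / L couplings. Writes a CSV of per-method results and a JSON
#' report to `cfg$output_dir`.
#'
#' @param cfg A `run_config`.
#' @return Object of class `eval_report`: list with `results` (data frame:
#'   method, k, ppv, average_precision, n_true), `orientation` (data frame of
#'   both_toward/mixed/both_away fractions per pair set), `ranking`, `maps`,
#'   `output_dir`.
#' @export
run_eval <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  s <- .cfg_structure(cfg)
  cm <- .cfg_couplings(cfg, s)
  cc <- .cfg_contact_maps(cfg, s)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  rp <- rank_pairs(cm, cfg$min_sep)
  k <- max(1L, floor(cfg$k_rule * s$L))
  res <- do.call(rbind, lapply(cfg$methods, function(m) {
    ev <- evaluate_ranking(rp, cc$maps[[m]], k)
    data.frame(method = m, k = ev$k, ppv = ev$ppv,
               average_precision = ev$average_precision,
               n_true = ev$n_true, stringsAsFactors = FALSE)
  }))

  ori_sets <- list(all_pairs = eligible_pairs(s$L, cfg$min_sep))
  for (m in cfg$methods) ori_sets[[paste0("contacts_", m)]] <- cc$maps[[m]]
  for (frac in c(0.25, 0.5, 1)) {
    kk <- min(nrow(rp), max(1L, floor(frac * s$L)))
    ori_sets[[sprintf("top_%gL", frac)]] <- rp[seq_len(kk), c("i", "j")]
  }
  ori <- do.call(rbind, lapply(names(ori_sets), function(nmset) {
    os <- orientation_summary(s, ori_sets[[nmset]])
    data.frame(set = nmset, n_pairs = os$n_pairs,
               both_toward = os$fractions[["both_toward"]],
               mixed = os$fractions[["mixed"]],
               both_away = os$fractions[["both_away"]],
               stringsAsFactors = FALSE)
  }))

  write.csv(res, file.path(cfg$output_dir, "eval_results.csv"), row.names = FALSE)
  write.csv(ori, file.path(cfg$output_dir, "orientation_results.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(L = s$L, k = k, seed = cfg$seed, cutoff_mode = cfg$cutoff_mode,
         results = res, orientation = ori),
    file.path(cfg$output_dir, "eval_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")

  structure(list(results = res, orientation = ori, ranking = rp,
                 maps = cc$maps, L = s$L, k = k,
                 output_dir = cfg$output_dir),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report: L =", x$L, "| k =", x$k, "\n")
  print(x$results, row.names = FALSE, digits = 3)
  cat("\norientation (both_toward fraction):\n")
  print(x$orientation[, c("set", "n_pairs", "both_toward")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
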
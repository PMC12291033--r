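#' Specification for a synthetic multiassay dataset
#'
#' Defines the study conditions emulated by [simulate_multiassay()]: a set
#' of LC-MS blocks over common samples, a shared latent structure driving
#' the response, and planted "compounds" that each emit several ions
#' (adducts and 13C isotopologues) with exact mass relationships, shared
#' within-assay retention time and correlated intensities across assays.
#'
#' `effect_size` is the between-class shift (classification) or the slope
#' on the standardized compound signal (regression) of the per-compound
#' log-intensity.  The default, `sqrt(2 * (1 + noise_sd^2)) * qnorm(0.8)`,
#' makes every planted ion's univariate class-separation AUC approximately
#' 0.8 on a held-out sample.
#'
#' @param N number of samples.
#' @param blocks list of lists with `assay`, `polarity`, `M` (features).
#' @param R_true latent rank of the shared structure (regression task).
#' @param n_compounds number of planted signal compounds.
#' @param p_extra_adduct probability of each non-identity same-polarity
#'   adduct rule per compound/assay.
#' @param p_isotopologue probability that an emitted adduct also carries a
#'   +1 isotopologue (a +2 follows with the same conditional probability).
#' @param p_assay probability a compound is detectable in a given assay
#'   (at least one assay is guaranteed).
#' @param effect_size association strength, see above; `0` plants no signal.
#' @param noise_sd ion-level lognormal noise sd (log scale).
#' @param mz_jitter_ppm uniform m/z measurement jitter (ppm).
#' @param rt_jitter_s uniform RT jitter per ion (seconds).
#' @param task `"classification"` or `"regression"`.
#' @param anchor_compound plant compound 1 as a bilirubin-like series:
#'   neutral mass 584.2634 Da, present in every assay, with `[M+H]+` and
#'   `[M+Na]+` (plus their +1 isotopologues) in positive assays and
#'   `[M-H]-` in negative assays.
#' @param seed integer seed; identical specs give bit-identical datasets.
#' @return list of class `"sim_spec"`.
#' @export
sim_spec <- function(N = 200,
                     blocks = list(
                       list(assay = "HILIC+", polarity = "positive", M = 300),
                       list(assay = "LRPC+", polarity = "positive", M = 300),
                       list(assay = "LRPC-", polarity = "negative", M = 300)),
                     R_true = 2,
                     n_compounds = 8,
                     p_extra_adduct = 0.4,
                     p_isotopologue = 0.5,
                     p_assay = 0.7,
                     effect_size = NULL,
                     noise_sd = 0.3,
                     mz_jitter_ppm = 1,
                     rt_jitter_s = 0.5,
                     task = c("classification", "regression"),
                     anchor_compound = TRUE,
                     seed = 1) {
  task <- match.arg(task)
  if (is.null(effect_size))
    effect_size <- sqrt(2 * (1 + noise_sd^2)) * stats::qnorm(0.8)
  stopifnot(N >= 4, length(blocks) >= 1, R_true >= 1, n_compounds >= 1,
            effect_size >= 0, noise_sd >= 0, mz_jitter_ppm >= 0,
            rt_jitter_s >= 0)
  structure(list(N = N, blocks = blocks, R_true = R_true,
                 n_compounds = n_compounds, p_extra_adduct = p_extra_adduct,
                 p_isotopologue = p_isotopologue, p_assay = p_assay,
                 effect_size = effect_size, noise_sd = noise_sd,
                 mz_jitter_ppm = mz_jitter_ppm, rt_jitter_s = rt_jitter_s,
                 task = task, anchor_compound = anchor_compound, seed = seed),
            class = "sim_spec")
}

# Draw neutral masses that cannot create spurious structural links: every
# pairwise mass difference stays > 0.05 Da away from every combination of
# rule-delta differences and isotopologue spacings the search could invoke.
draw_neutral_masses <- function(n, rules, max_isotopes = 3, anchor = NULL) {
  deltas <- rules$delta_mz
  shifts <- outer(deltas, deltas, "-")
  iso <- (-max_isotopes:max_isotopes) * C13_SPACING
  confusable <- unique(as.numeric(outer(as.numeric(shifts), iso, "+")))
  masses <- numeric(0)
  if (!is.null(anchor)) masses <- anchor
  guard <- 0
  while (length(masses) < n) {
    m <- stats::runif(1, 150, 900)
    ok <- all(vapply(masses, function(prev)
      min(abs(abs(m - prev) - abs(confusable))) > 0.05 &&
        abs(m - prev) > 0.05, TRUE))
    if (ok) masses <- c(masses, m)
    guard <- guard + 1
    if (guard > 10000) stop("cannot place ", n, " well-separated masses")
  }
  masses[seq_len(n)]
}

# RTs for all compounds in one assay, pairwise separated by > 6 s so that
# co-elution (the within-assay gate) never links different compounds.
draw_rts <- function(n, lo = 60, hi = 540, min_gap = 6) {
  rts <- numeric(0)
  guard <- 0
  while (length(rts) < n) {
    r <- stats::runif(1, lo, hi)
    if (!length(rts) || min(abs(r - rts)) > min_gap) rts <- c(rts, r)
    guard <- guard + 1
    if (guard > 10000) stop("cannot place ", n, " separated RTs")
  }
  rts
}

#' Simulate a multiassay LC-MS dataset with known ground truth
#'
#' Latent Gaussian scores drive both the response and the planted
#' compounds' base intensities.  Each compound receives a neutral
#' monoisotopic mass (uniform on 150-900 Da, rejection-sampled so that no
#' two compounds can be confused by any adduct/isotopologue rule), one
#' retention time per assay, and a set of ions whose m/z follow the shared
#' rule table exactly, plus ppm-scale jitter.  Ion intensities are
#' `compound intensity x ion yield x lognormal noise`, with Dirichlet ion
#' yields dominated by the identity adduct.  Non-signal features are
#' structured noise (per-block latent background factors plus i.i.d.
#' noise).  Intensities are emitted on the natural (exponentiated) scale.
#'
#' @param spec a [sim_spec()].
#' @return list with `dataset` (a `multiblock_dataset`) and `truth`:
#'   `ions` (per planted ion: feature_id, assay, compound, rule, k_iso,
#'   true mz/rt, yield), `signal_features`, `structural_partition` and
#'   `cluster_partition` (named compound labels over planted ions),
#'   `R_true`, `spec`.
#' @export
simulate_multiassay <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  rules <- default_adduct_rules()
  with_seed(spec$seed, {
    N <- spec$N
    B <- length(spec$blocks)
    n_c <- spec$n_compounds

    ## response and compound-level signal
    if (spec$task == "classification") {
      y <- stats::rbinom(N, 1, 0.5)
      while (length(unique(y)) < 2) y <- stats::rbinom(N, 1, 0.5)
      signal <- matrix(rep(y - 0.5, n_c), N, n_c)       # class shift direction
    } else {
      Z <- matrix(stats::rnorm(N * spec$R_true), N, spec$R_true)
      a <- rep(1 / sqrt(spec$R_true), spec$R_true)
      y <- as.numeric(Z %*% a) + 0.5 * stats::rnorm(N)
      L <- matrix(stats::rnorm(n_c * spec$R_true), n_c, spec$R_true)
      L <- L / sqrt(rowSums(L^2))
      signal <- Z %*% t(L)                              # N x n_c, unit variance
    }
    base <- spec$effect_size * signal +
      matrix(stats::rnorm(N * n_c), N, n_c)             # compound log intensity

    ## planted ion catalogue
    anchor <- if (spec$anchor_compound) 584.2634 else NULL
    masses <- draw_neutral_masses(n_c, rules, anchor = anchor)
    assay_names <- vapply(spec$blocks, `[[`, "", "assay")
    polarities <- vapply(spec$blocks, `[[`, "", "polarity")
    rts <- lapply(seq_len(B), function(b) draw_rts(n_c))
    present <- matrix(stats::runif(n_c * B) < spec$p_assay, n_c, B)
    for (ci in seq_len(n_c))
      if (!any(present[ci, ])) present[ci, sample.int(B, 1)] <- TRUE
    if (spec$anchor_compound) present[1, ] <- TRUE

    ions <- list()
    for (ci in seq_len(n_c)) {
      for (b in which(present[ci, ])) {
        pol <- polarities[b]
        rl <- rules[rules$polarity == pol, , drop = FALSE]
        id_rule <- if (pol == "positive") "[M+H]+" else "[M-H]-"
        picked <- id_rule
        extra <- setdiff(rl$name, id_rule)
        if (spec$anchor_compound && ci == 1) {
          if (pol == "positive") picked <- c("[M+H]+", "[M+Na]+")
        } else if (length(extra)) {
          picked <- c(picked, extra[stats::runif(length(extra)) < spec$p_extra_adduct])
        }
        for (ad in picked) {
          k_max <- 0
          if (spec$anchor_compound && ci == 1 && pol == "positive") {
            k_max <- 1
          } else {
            while (k_max < 2 && stats::runif(1) < spec$p_isotopologue)
              k_max <- k_max + 1
          }
          for (k in 0:k_max) {
            delta <- rl$delta_mz[rl$name == ad]
            ions[[length(ions) + 1]] <- data.frame(
              compound = ci, block = b, assay = assay_names[b],
              polarity = pol, rule = ad, k_iso = k,
              mz_true = masses[ci] + delta + k * C13_SPACING,
              rt_true = rts[[b]][ci],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    ions <- do.call(rbind, ions)
    Mb <- vapply(spec$blocks, `[[`, 1, "M")
    n_sig_b <- tabulate(ions$block, B)
    if (any(n_sig_b > Mb))
      stop("more planted ions than features in block(s): ",
           paste(assay_names[n_sig_b > Mb], collapse = ", "))

    ## Dirichlet yields per compound/assay, identity adduct favored
    ions$yield <- NA_real_
    for (ci in seq_len(n_c)) for (b in which(present[ci, ])) {
      sel <- ions$compound == ci & ions$block == b
      alpha <- ifelse(ions$rule[sel] %in% c("[M+H]+", "[M-H]-") &
                        ions$k_iso[sel] == 0, 6, 1)
      gam <- stats::rgamma(sum(sel), shape = alpha)
      ions$yield[sel] <- gam / sum(gam)
    }

    ## observed m/z and RT with jitter
    ions$mz <- ions$mz_true *
      (1 + spec$mz_jitter_ppm * 1e-6 * stats::runif(nrow(ions), -1, 1))
    ions$rt <- pmax(0, ions$rt_true +
                      stats::runif(nrow(ions), -spec$rt_jitter_s, spec$rt_jitter_s))

    ## assemble blocks
    sample_ids <- sprintf("S%03d", seq_len(N))
    blocks <- vector("list", B)
    ions$feature_id <- NA_character_
    for (b in seq_len(B)) {
      M <- Mb[b]
      sel <- which(ions$block == b)
      pos <- sort(sample.int(M, length(sel)))           # ion column positions
      logX <- matrix(12 + stats::rnorm(N * M, sd = 0.25), N, M)
      n_noise <- M - length(sel)
      if (n_noise > 0) {
        Fb <- matrix(stats::rnorm(N * 4), N, 4)         # background structure
        Lb <- matrix(stats::rnorm(n_noise * 4, sd = 0.5), n_noise, 4)
        noise_cols <- setdiff(seq_len(M), pos)
        logX[, noise_cols] <- logX[, noise_cols] + Fb %*% t(Lb) +
          matrix(stats::rnorm(N * n_noise, sd = 0.5), N, n_noise)
      }
      mzs <- stats::runif(M, 70, 1000)
      rts_noise <- stats::runif(M, 30, 570)
      for (s in seq_along(sel)) {
        i <- sel[s]
        logX[, pos[s]] <- 12 + log(ions$yield[i]) + base[, ions$compound[i]] +
          spec$noise_sd * stats::rnorm(N)
        mzs[pos[s]] <- ions$mz[i]
        rts_noise[pos[s]] <- ions$rt[i]
      }
      fid <- sprintf("%s_%.4f_%.2f", assay_names[b], mzs, rts_noise)
      fid <- make.unique(fid, sep = "~")
      ions$feature_id[sel] <- fid[pos]
      fm <- feature_meta(fid, assay_names[b], mzs, rts_noise, polarities[b])
      X <- exp(logX)
      rownames(X) <- sample_ids
      blocks[[b]] <- new_block(X, fm)
    }
    names(y) <- sample_ids
    dataset <- align_blocks(blocks, y, y_name = spec$task)
    part <- ions$compound
    names(part) <- ions$feature_id
    list(dataset = dataset,
         truth = list(ions = ions,
                      signal_features = ions$feature_id,
                      structural_partition = part,
                      cluster_partition = part,
                      R_true = spec$R_true,
                      spec = spec))
  })
}

#' Write a simulated dataset to standard files
#'
#' Writes one feature table and metadata table per block, a response table,
#' and ground-truth sidecar files (`truth_ions.csv`,
#' `truth_partition.csv`) into `dir`.
#'
#' @param sim result of [simulate_multiassay()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (b in sim$dataset$blocks) {
    safe <- gsub("-", "neg", gsub("\\+", "pos", b$assay))
    safe <- gsub("[^0-9A-Za-z]", "_", safe)
    p <- file.path(dir, paste0("block_", safe, ".csv"))
    write_feature_table(b, p)
    m <- file.path(dir, paste0("meta_", safe, ".csv"))
    fm <- b$features
    fm$mz <- sprintf("%.10g", fm$mz)
    fm$rt <- sprintf("%.10g", fm$rt)
    utils::write.table(fm, m, sep = ",", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p, m)
  }
  yp <- file.path(dir, "response.csv")
  utils::write.table(data.frame(sample_id = names(sim$dataset$y),
                                y = sprintf("%.10g", sim$dataset$y)),
                     yp, sep = ",", row.names = FALSE, quote = FALSE)
  ip <- file.path(dir, "truth_ions.csv")
  utils::write.table(sim$truth$ions, ip, sep = ",", row.names = FALSE, quote = FALSE)
  pp <- file.path(dir, "truth_partition.csv")
  utils::write.table(data.frame(feature_id = names(sim$truth$structural_partition),
                                compound = unname(sim$truth$structural_partition)),
                     pp, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(c(paths, yp, ip, pp))
}
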
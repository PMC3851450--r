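## Synthetic labeled-sequence generator. Emulates the statistical structure
## the classifiers exploit: class-conditional residue compositions (plastid
## vs non-plastid differing in 11 residues), dipeptide-level coupling via a
## class-biased first-order Markov chain, and an optional N-terminal
## S/T/A-rich prefix emulating a transit-peptide-like region. It does not
## emulate protein evolution or homology structure.

## Swiss-Prot-like background residue frequencies (alphabetical order).
BASE_COMPOSITION <- local({
  f <- c(A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0674, F = 0.0386,
         G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0582, L = 0.0965,
         M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
         S = 0.0660, T = 0.0535, V = 0.0687, W = 0.0110, Y = 0.0292)
  f / sum(f)
})

## Multiply frequencies of a residue subset by per-residue factors, then
## rescale the subset back to its original total mass: residues outside the
## subset are left exactly unchanged and the vector still sums to 1.
shift_within_subset <- function(freq, up = character(0), down = character(0),
                                up_factor = 1.3, down_factor = 0.7) {
  subset <- c(up, down)
  mass <- sum(freq[subset])
  freq[up] <- freq[up] * up_factor
  freq[down] <- freq[down] * down_factor
  freq[subset] <- freq[subset] * mass / sum(freq[subset])
  freq
}

#' Define a synthetic class profile
#'
#' @param name class label.
#' @param freq residue frequency vector (20 values summing to 1,
#'   alphabetical order).
#' @param coupling dipeptide coupling strength in \[0, 1): mixing weight of
#'   a class-biased first-order Markov transition against independent draws.
#' @param coupling_seed integer seed fixing the class's transition bias.
#' @param coupling_sd spread of the log-scale transition bias.
#' @param n_terminal_bias optional list describing a transit-peptide-like
#'   prefix: `freq` (20-vector), `min_len`, `max_len` (prefix length drawn
#'   uniformly, capped at a third of the sequence).
#' @param length_meanlog,length_sdlog,min_length log-normal sequence length
#'   distribution (median ~300, sigma 0.4) with a floor of 80 residues.
#' @return a `class_profile` list.
#' @export
class_profile <- function(name, freq, coupling = 0.25, coupling_seed = 1L,
                          coupling_sd = 0.6, n_terminal_bias = NULL,
                          length_meanlog = log(300), length_sdlog = 0.4,
                          min_length = 80L) {
  freq <- freq[AA_ALPHABET20]
  if (any(is.na(freq)) || any(freq < 0) || abs(sum(freq) - 1) > 1e-9)
    stop_usage("freq must be a non-negative 20-vector summing to 1")
  if (coupling < 0 || coupling >= 1) stop_usage("coupling must be in [0, 1)")
  structure(list(name = name, freq = freq, coupling = coupling,
                 coupling_seed = as.integer(coupling_seed),
                 coupling_sd = coupling_sd,
                 n_terminal_bias = n_terminal_bias,
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 min_length = as.integer(min_length)),
            class = "class_profile")
}

#' Default class profiles
#'
#' Six profiles: `plastid`, `nonplastid` (phase I) and the four plastid
#' types `chloroplast`, `chromoplast`, `etioplast`, `amyloplast` (phase II).
#' The plastid and non-plastid compositions differ in exactly the 11
#' residues A, C, I, M, P, V, D, H, K, S, W (A, I, M, P, V, S enriched and
#' C, D, H, K, W depleted in plastids); the four subtypes share the plastid
#' composition and differ from it in smaller, pairwise-distinct residue
#' subsets, making phase II the harder problem. All plastid-family profiles
#' carry an S/T/A-rich N-terminal prefix; each class also has its own
#' dipeptide-level transition bias.
#'
#' @param delta effect size >= 0: scales every profile deviation (composition
#'   shifts, prefix enrichment, transition bias) away from the shared
#'   background; `delta = 0` collapses all classes onto the background
#'   composition (the null configuration), 1 is the default study setting.
#' @return named list of six `class_profile` objects.
#' @export
default_profiles <- function(delta = 1) {
  if (delta < 0) stop_usage("delta must be >= 0")
  base <- BASE_COMPOSITION
  interp <- function(target) base + delta * (target - base)
  plastid_f <- shift_within_subset(base,
                                   up = c("A", "I", "M", "P", "V", "S"),
                                   down = c("C", "D", "H", "K", "W"),
                                   up_factor = 1.30, down_factor = 0.70)
  sub_shift <- function(up, down)
    shift_within_subset(plastid_f, up, down, up_factor = 1.20, down_factor = 0.80)
  targets <- list(
    plastid     = plastid_f,
    nonplastid  = base,
    chloroplast = sub_shift(c("A", "G"), c("E", "K")),
    chromoplast = sub_shift(c("L", "V"), c("F", "P")),
    etioplast   = sub_shift(c("S", "T"), c("N", "D")),
    amyloplast  = sub_shift(c("I", "M"), c("Q", "R")))
  prefix_target <- local({
    p <- base
    p[c("S", "T", "A")] <- p[c("S", "T", "A")] * 2.5
    p[c("D", "E")] <- p[c("D", "E")] * 0.4
    p / sum(p)
  })
  seeds <- c(plastid = 101L, nonplastid = 202L, chloroplast = 303L,
             chromoplast = 404L, etioplast = 505L, amyloplast = 606L)
  out <- lapply(names(targets), function(nm) {
    ntb <- NULL
    if (nm != "nonplastid")
      ntb <- list(freq = interp(prefix_target), min_len = 30L, max_len = 60L)
    class_profile(nm, freq = interp(targets[[nm]]),
                  coupling = 0.25, coupling_seed = seeds[[nm]],
                  coupling_sd = 0.6 * delta, n_terminal_bias = ntb)
  })
  names(out) <- names(targets)
  out
}

## Class-biased transition matrix with the profile composition as its exact
## stationary distribution: a seeded log-normal perturbation of the product
## joint f x f is Sinkhorn-balanced so both marginals equal f, then divided
## by the row marginal. Mixing this with independent draws preserves
## stationarity, so pooled residue frequencies converge to the profile.
biased_transition <- function(profile) {
  f <- profile$freq
  ## the class bias is fixed by its own seed; preserve the caller's RNG state
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(profile$coupling_seed)
  Z <- matrix(rnorm(400, sd = profile$coupling_sd), 20, 20)
  J <- outer(f, f) * exp(Z)
  for (it in 1:200) {
    J <- J * (f / rowSums(J))
    J <- t(t(J) * (f / colSums(J)))
    if (max(abs(rowSums(J) - f)) < 1e-12) break
  }
  B <- J / rowSums(J)
  iid <- matrix(f, 20, 20, byrow = TRUE)
  Tm <- (1 - profile$coupling) * iid + profile$coupling * B
  dimnames(Tm) <- list(AA_ALPHABET20, AA_ALPHABET20)
  Tm
}

## Expected fraction of residues contributed by the N-terminal prefix,
## evaluated on a deterministic length-quantile grid (used to compensate the
## body composition so the pooled composition matches the profile).
expected_prefix_fraction <- function(profile) {
  ntb <- profile$n_terminal_bias
  if (is.null(ntb)) return(0)
  q <- stats::qlnorm(seq(0.0005, 0.9995, length.out = 400),
                     profile$length_meanlog, profile$length_sdlog)
  L <- pmax(round(q), profile$min_length)
  lens <- ntb$min_len:ntb$max_len
  pre <- vapply(L, function(l) mean(pmin(lens, l %/% 3L)), numeric(1))
  sum(pre) / sum(L)
}

sample_markov <- function(n, start_freq, trans_cum) {
  ## trans_cum: 20 x 20 row-wise cumulative transition probabilities
  idx <- integer(n)
  idx[1] <- findInterval(runif(1), cumsum(start_freq)) + 1L
  u <- runif(n)
  for (i in seq_len(n - 1L))
    idx[i + 1L] <- findInterval(u[i], trans_cum[idx[i], ]) + 1L
  idx
}

#' Generate a labeled synthetic dataset
#'
#' Draws `n_per_class` sequences from each profile. Sequence lengths are
#' log-normal with a floor; plastid-family sequences start with a
#' transit-peptide-like prefix drawn i.i.d. from the prefix composition; the
#' body is drawn from the class's Markov chain. The body composition is
#' compensated for the prefix so that the pooled residue frequencies of a
#' class converge to its profile frequencies. Reproducible given the seed.
#'
#' @param profiles named list of `class_profile` objects (e.g.
#'   [default_profiles]).
#' @param n_per_class sequences per class (single value or per-class vector).
#' @param seed integer seed.
#' @return a `protein_records` table with an extra `label` column.
#' @export
generate_dataset <- function(profiles, n_per_class, seed = 1L) {
  if (any(n_per_class < 1)) stop_usage("n_per_class must be >= 1")
  n_per_class <- rep_len(n_per_class, length(profiles))
  set.seed(seed)
  out <- vector("list", length(profiles))
  for (k in seq_along(profiles)) {
    pr <- profiles[[k]]
    n <- n_per_class[k]
    pi_pre <- expected_prefix_fraction(pr)
    body_f <- pr$freq
    if (pi_pre > 0) {
      body_f <- (pr$freq - pi_pre * pr$n_terminal_bias$freq) / (1 - pi_pre)
      if (any(body_f < 0))
        stop_usage(sprintf(
          "profile '%s': prefix enrichment too strong to compensate", pr$name))
    }
    body_profile <- pr
    body_profile$freq <- body_f / sum(body_f)
    tc <- t(apply(biased_transition(body_profile), 1, cumsum))
    seqs <- character(n)
    for (i in seq_len(n)) {
      L <- max(round(rlnorm(1, pr$length_meanlog, pr$length_sdlog)),
               pr$min_length)
      pre_idx <- integer(0)
      if (!is.null(pr$n_terminal_bias)) {
        plen <- min(sample(pr$n_terminal_bias$min_len:pr$n_terminal_bias$max_len, 1),
                    L %/% 3L)
        pre_idx <- sample.int(20L, plen, replace = TRUE,
                              prob = pr$n_terminal_bias$freq)
      }
      body_idx <- sample_markov(L - length(pre_idx), body_profile$freq, tc)
      seqs[i] <- paste(AA_ALPHABET20[c(pre_idx, body_idx)], collapse = "")
    }
    df <- protein_records(id = sprintf("%s_%04d", pr$name, seq_len(n)),
                          sequence = seqs)
    df$label <- pr$name
    out[[k]] <- df
  }
  res <- do.call(rbind, out)
  class(res) <- c("protein_records", "data.frame")
  res
}

#' Build the synthetic two-phase benchmark
#'
#' Deterministically generates phase-I (plastid vs non-plastid) and phase-II
#' (four plastid types) training and independent sets at reduced scale —
#' 400 sequences per phase-I class and 150 per plastid type by default, with
#' independent sets of 100 and 40 per class — and optionally writes them as
#' FASTA files plus TSV label manifests.
#'
#' @param seed integer seed.
#' @param out_dir optional output directory for FASTA + manifest files.
#' @param n1_train,n1_test per-class sizes for phase I.
#' @param n2_train,n2_test per-class sizes for phase II.
#' @param delta effect size passed to [default_profiles].
#' @return list with `phase1_train`, `phase1_test`, `phase2_train`,
#'   `phase2_test` (labeled `protein_records`) and `manifest` (data frame of
#'   set/class counts).
#' @export
make_benchmark <- function(seed = 1L, out_dir = NULL,
                           n1_train = 400L, n1_test = 100L,
                           n2_train = 150L, n2_test = 40L, delta = 1) {
  pr <- default_profiles(delta)
  p1 <- pr[c("plastid", "nonplastid")]
  p2 <- pr[c("chloroplast", "chromoplast", "etioplast", "amyloplast")]
  sets <- list(
    phase1_train = generate_dataset(p1, n1_train, seed = seed),
    phase1_test  = generate_dataset(p1, n1_test,  seed = seed + 1000L),
    phase2_train = generate_dataset(p2, n2_train, seed = seed + 2000L),
    phase2_test  = generate_dataset(p2, n2_test,  seed = seed + 3000L))
  ## disambiguate ids across sets
  for (nm in names(sets)) sets[[nm]]$id <- paste0(nm, ".", sets[[nm]]$id)
  manifest <- do.call(rbind, lapply(names(sets), function(nm) {
    tb <- table(sets[[nm]]$label)
    data.frame(set = nm, class = names(tb), n = as.integer(tb),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(sets)) {
      write_fasta(sets[[nm]], file.path(out_dir, paste0(nm, ".fasta")))
      write.table(sets[[nm]][, c("id", "label")],
                  file.path(out_dir, paste0(nm, ".labels.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(manifest, file.path(out_dir, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  c(sets, list(manifest = manifest))
}
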
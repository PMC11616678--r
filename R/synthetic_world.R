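# Seeded generator of a toy bilingual protein universe.
#
# Amino-acid sequences are drawn from a family-specific motif model arranged
# in a 3-level fold/superfamily/family hierarchy; the 3Di-like structure
# string is a fixed local function of the AA sequence (windowed hash mapped
# through a skewed token distribution, then run-length smoothed), corrupted by
# independent per-position noise. Per-protein pLDDT-like quality scores come
# from a two-component Beta mixture so a controllable fraction falls below 70.
#
# The generator reproduces the three statistical properties the real 3Di
# alphabet shows on large predicted-structure collections: the mapping is
# learnable from local sequence context, heavily imbalanced (a few states --
# here v, d, p -- cover over half of all residues) and locally smooth
# (secondary-structure-like runs).

# Token order used by the skewed (Zipf) target distribution; v, d, p first so
# the over-represented states carry familiar names.
TDI_ZIPF_ORDER <- c("v", "d", "p", "a", "c", "e", "f", "g", "h", "i",
                    "k", "l", "m", "n", "q", "r", "s", "t", "w", "y")

#' Configuration of the synthetic bilingual world
#'
#' @param n_proteins number of proteins.
#' @param length_range integer `(min, max)` protein length.
#' @param window odd width of the AA context that determines a structure
#'   token (the map reads the window's center and right neighbour; smoothing
#'   widens the effective context by one on each side).
#' @param noise_rate probability that a structure token is resampled
#'   uniformly, independently per position.
#' @param skew Zipf exponent of the target 3Di token distribution (> 0);
#'   the default 1 makes the top three tokens cover over half the residues.
#' @param n_clusters total number of sequence clusters (nested inside
#'   families).
#' @param hierarchy_shape integer triple `(n_folds, n_superfams_per_fold,
#'   n_fams_per_superfam)`.
#' @param low_plddt_frac fraction of proteins drawn from the low-quality
#'   mixture component (most of which fall below pLDDT 70).
#' @param seed integer seed; all randomness in [generate_world()] flows from
#'   it.
#' @return a `world_config` list.
#' @export
world_config <- function(n_proteins = 5000, length_range = c(30L, 60L),
                         window = 3L, noise_rate = 0.05, skew = 1,
                         n_clusters = 200L, hierarchy_shape = c(4L, 3L, 2L),
                         low_plddt_frac = 0.15, seed = 42L) {
  stopifnot(n_proteins >= 1, length(length_range) == 2,
            length_range[1] >= 1, length_range[1] <= length_range[2],
            window %% 2 == 1, window >= 1,
            noise_rate >= 0, noise_rate <= 1, skew > 0,
            n_clusters >= 1, length(hierarchy_shape) == 3,
            all(hierarchy_shape >= 1),
            low_plddt_frac >= 0, low_plddt_frac <= 1)
  structure(list(
    n_proteins = as.integer(n_proteins),
    length_range = as.integer(length_range),
    window = as.integer(window),
    noise_rate = noise_rate, skew = skew,
    n_clusters = as.integer(n_clusters),
    hierarchy_shape = as.integer(hierarchy_shape),
    low_plddt_frac = low_plddt_frac,
    seed = as.integer(seed)
  ), class = "world_config")
}

# Zipf probabilities over TDI_ZIPF_ORDER.
zipf_probs <- function(skew) {
  w <- seq_len(20)^(-skew)
  w / sum(w)
}

# Low-discrepancy hash of a small non-negative integer into [0, 1).
golden_hash <- function(h) (h * 0.6180339887498949) %% 1

#' Map an amino-acid sequence to its noise-free structure string
#'
#' The fixed surjective map g: each position's token is determined by the
#' (center, right-neighbour) amino acids inside the context window, hashed
#' into a Zipf-skewed distribution over the 20 3Di letters, followed by a
#' majority vote over each 3-window (ties keep the center) that produces
#' secondary-structure-like runs.
#'
#' @param aa_seq amino-acid string.
#' @param window odd context width (the map is defined for any odd width; it
#'   reads the two central positions of the window).
#' @param skew Zipf exponent of the token distribution.
#' @return 3Di string of the same length.
#' @export
apply_structure_map <- function(aa_seq, window = 3L, skew = 1) {
  n <- nchar(aa_seq)
  if (n == 0) return("")
  idx <- match(split_chars(aa_seq), c(AA_LETTERS, "X"))
  if (anyNA(idx)) stop("invalid amino-acid sequence", call. = FALSE)
  nxt <- c(idx[-1], 0L)                       # boundary char -> 0
  u <- golden_hash(idx * 22 + nxt)
  cum <- cumsum(zipf_probs(skew))
  tok <- findInterval(u, cum) + 1L            # 1..20 into TDI_ZIPF_ORDER
  # run-length smoothing: majority over {i-1, i, i+1}, tie keeps center
  if (n >= 3) {
    left <- c(tok[1], tok[-n]); right <- c(tok[-1], tok[n])
    flip <- left == right & left != tok
    flip[c(1, n)] <- FALSE
    tok[flip] <- left[flip]
  }
  paste(TDI_ZIPF_ORDER[tok], collapse = "")
}

mutate_aa <- function(idx, rate) {
  hit <- stats::runif(length(idx)) < rate
  idx[hit] <- sample.int(20L, sum(hit), replace = TRUE)
  idx
}

#' Generate the synthetic bilingual protein world
#'
#' Deterministic given `cfg$seed`. Families inherit a mutated copy of their
#' superfamily motif, superfamilies of their fold motif; proteins are mutated,
#' randomly cropped copies of their family motif, so same-family pairs share
#' more sequence identity than cross-family pairs. Clusters are nested inside
#' families.
#'
#' @param cfg a [world_config()].
#' @return tibble of protein records with columns `id`, `aa_seq`, `tdi_seq`,
#'   `plddt`, `cluster_id`, `hierarchy` (dot-separated `fold.superfam.family`),
#'   `split` (all `"unassigned"`).
#' @examples
#' w <- generate_world(world_config(n_proteins = 20, seed = 1))
#' dplyr::count(w, hierarchy)
#' @export
generate_world <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  withr::with_seed(cfg$seed, {
    shape <- cfg$hierarchy_shape
    n_folds <- shape[1]; n_sf <- shape[2]; n_fam <- shape[3]
    n_families <- n_folds * n_sf * n_fam
    lmax <- cfg$length_range[2]

    # per-level mutation rates: high between folds (independent motifs),
    # moderate between superfamilies / families, low within a family
    rate_sf <- 0.30; rate_fam <- 0.15; rate_prot <- 0.06

    fams <- list(); labels <- character(0)
    for (f in seq_len(n_folds)) {
      fold_motif <- sample.int(20L, lmax, replace = TRUE)
      for (s in seq_len(n_sf)) {
        sf_motif <- mutate_aa(fold_motif, rate_sf)
        for (m in seq_len(n_fam)) {
          fams[[length(fams) + 1L]] <- mutate_aa(sf_motif, rate_fam)
          labels <- c(labels, sprintf("f%d.s%d.m%d", f, s, m))
        }
      }
    }

    fam_of <- rep_len(seq_len(n_families), cfg$n_proteins)
    clusters_per_fam <- max(1L, as.integer(round(cfg$n_clusters / n_families)))

    lens <- sample(seq(cfg$length_range[1], lmax), cfg$n_proteins,
                   replace = TRUE)
    aa_seq <- character(cfg$n_proteins)
    tdi_seq <- character(cfg$n_proteins)
    cluster_id <- character(cfg$n_proteins)
    member_count <- integer(n_families)
    for (i in seq_len(cfg$n_proteins)) {
      fam <- fam_of[i]
      start <- sample.int(lmax - lens[i] + 1L, 1L)
      idx <- mutate_aa(fams[[fam]][start:(start + lens[i] - 1L)], rate_prot)
      aa_seq[i] <- paste(AA_LETTERS[idx], collapse = "")
      tdi <- apply_structure_map(aa_seq[i], cfg$window, cfg$skew)
      if (cfg$noise_rate > 0) {
        tchars <- split_chars(tdi)
        hit <- stats::runif(lens[i]) < cfg$noise_rate
        tchars[hit] <- sample(TDI_LETTERS, sum(hit), replace = TRUE)
        tdi <- paste(tchars, collapse = "")
      }
      tdi_seq[i] <- tdi
      member_count[fam] <- member_count[fam] + 1L
      cluster_id[i] <- sprintf("%s_c%d", labels[fam],
                               (member_count[fam] - 1L) %% clusters_per_fam + 1L)
    }

    low <- stats::runif(cfg$n_proteins) < cfg$low_plddt_frac
    plddt <- numeric(cfg$n_proteins)
    plddt[low]  <- 40 + 60 * stats::rbeta(sum(low), 2, 5)
    plddt[!low] <- 40 + 60 * stats::rbeta(sum(!low), 8, 1.5)

    tibble::tibble(
      id = sprintf("sp%05d", seq_len(cfg$n_proteins)),
      aa_seq = aa_seq, tdi_seq = tdi_seq,
      plddt = round(plddt, 2),
      cluster_id = cluster_id,
      hierarchy = labels[fam_of],
      split = "unassigned")
  })
}

#' Map 8-state DSSP secondary structure to 3 states
#'
#' `G,H,I -> H` (helix), `B,E -> E` (strand), `-,T,S -> O` (other).
#'
#' @param ss8 string (or vector of strings) over `GHIBE-TS`.
#' @return string(s) over `HEO`.
#' @export
dssp8_to_ss3 <- function(ss8) {
  map <- c(G = "H", H = "H", I = "H", B = "E", E = "E",
           "-" = "O", T = "O", S = "O")
  vapply(ss8, function(s) {
    chars <- map[split_chars(s)]
    if (anyNA(chars)) stop("invalid 8-state code in: ", s, call. = FALSE)
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Fixed secondary-structure preference of each synthetic 3Di token, mirroring
# the helix/strand/other affinities reported for the real alphabet.
TDI_SS3_PREF <- c(v = "H", l = "H", e = "E", i = "E", k = "E", t = "E",
                  w = "E", y = "E", d = "O", p = "O", a = "O", c = "H",
                  f = "O", g = "O", h = "H", m = "E", n = "O", q = "H",
                  r = "O", s = "O")

#' Draw synthetic per-residue 3-state secondary-structure labels
#'
#' Each residue gets its 3Di token's preferred class, flipped to a uniform
#' random class with probability `flip_rate`; used to exercise the
#' token/secondary-structure co-occurrence analysis without real DSSP input.
#'
#' @param records tibble with `tdi_seq`.
#' @param flip_rate label noise.
#' @param seed integer seed.
#' @return character vector of `HEO` strings aligned to `tdi_seq`.
#' @export
synthetic_ss3 <- function(records, flip_rate = 0.1, seed = 1L) {
  withr::with_seed(seed, {
    vapply(records$tdi_seq, function(tdi) {
      lab <- unname(TDI_SS3_PREF[split_chars(tdi)])
      hit <- stats::runif(length(lab)) < flip_rate
      lab[hit] <- sample(c("H", "E", "O"), sum(hit), replace = TRUE)
      paste(lab, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Token / secondary-structure co-occurrence table
#'
#' Cross-tabulates 3Di tokens against aligned per-residue 3-state secondary
#' structure labels.
#'
#' @param records tibble with `tdi_seq`.
#' @param ss3 character vector of `HEO` strings, aligned to `tdi_seq`.
#' @return list with `counts` (20 x 3 integer matrix) and `props` (rows
#'   renormalized to sum to 1; all-zero rows stay zero).
#' @export
ss3_cooccurrence <- function(records, ss3) {
  if (length(ss3) != nrow(records)) {
    stop("ss3 must hold one label string per record", call. = FALSE)
  }
  mism <- which(nchar(ss3) != nchar(records$tdi_seq))
  if (length(mism) > 0) {
    stop(sprintf("ss3 length mismatch for record '%s'", records$id[mism[1]]),
         call. = FALSE)
  }
  tok <- unlist(strsplit(paste(records$tdi_seq, collapse = ""), ""))
  lab <- unlist(strsplit(paste(ss3, collapse = ""), ""))
  counts <- table(factor(tok, levels = TDI_LETTERS),
                  factor(lab, levels = c("H", "E", "O")))
  counts <- matrix(as.integer(counts), 20, 3,
                   dimnames = list(TDI_LETTERS, c("H", "E", "O")))
  rs <- rowSums(counts)
  props <- counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, props = props)
}
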
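#' Cattle-like chromosome table
#'
#' Twenty-nine autosomes plus X (coded 30) with lengths proportional to the
#' bovine assembly, rescaled so the genome totals \code{genome_bp}. The
#' default 1.5 Gb, combined with the default 50 kb SNP spacing, yields a
#' medium-density panel of roughly 30 K mapped SNPs.
#'
#' @param genome_bp total genome size after rescaling.
#' @param n_autosomes number of autosomes kept (1..29).
#' @param include_x append the X chromosome as code 30.
#' @return data.frame with columns \code{id}, \code{length_bp}, \code{is_x}.
#' @export
default_chromosomes <- function(genome_bp = 1.5e9, n_autosomes = 29,
                                include_x = TRUE) {
  # approximate bovine chromosome sizes in Mb (autosomes 1..29, then X)
  mb <- c(158, 136, 121, 121, 120, 118, 110, 113, 105, 104, 107, 87, 83, 82,
          85, 81, 75, 66, 64, 72, 70, 61, 52, 62, 42, 52, 45, 46, 51, 139)
  stopifnot(n_autosomes >= 1, n_autosomes <= 29)
  sel <- c(seq_len(n_autosomes), if (include_x) 30L)
  len <- mb[sel] * 1e6
  len <- round(len * genome_bp / sum(len))
  data.frame(id = c(seq_len(n_autosomes), if (include_x) 30L),
             length_bp = len,
             is_x = c(rep(FALSE, n_autosomes), if (include_x) TRUE))
}

#' Simulation configuration for a closed line
#'
#' Defaults emulate a closed beef-cattle line founded by two half-sib bulls
#' (sharing a phantom sire) and 50 unrelated cows, bred for 8 discrete
#' generations with very few sires per generation so that pedigree inbreeding
#' accumulates to around 0.3. The growth phenotype (average daily gain,
#' kg/day) has a population mean near 0.83 and SD near 0.353 (heritability of
#' ADG is about 0.25 in this breed; only the inbreeding-linked part of the
#' genetic variance is modeled explicitly). Chromosome-specific inbreeding
#' depression defaults to -0.2 kg/day per unit chromosome IBD on chromosomes
#' 2, 4 and 10, zero elsewhere.
#'
#' @param n_founder_sires number of founder bulls (half sibs).
#' @param n_founder_dams number of founder cows.
#' @param n_generations discrete generations bred after the founders.
#' @param offspring_per_dam calves per dam per generation.
#' @param sires_per_generation sires sampled per generation (small values
#'   force inbreeding).
#' @param max_dams_per_generation cap on breeding females per generation.
#' @param chromosomes data.frame from [default_chromosomes()] (or the same
#'   columns).
#' @param snp_spacing_bp distance between mapped SNPs.
#' @param cm_per_mb recombination rate (uniform map, no interference).
#' @param maf_range range of founder minor-allele frequencies drawn per SNP.
#' @param depression_effects named numeric vector, chromosome id to kg/day
#'   per unit chromosome IBD fraction.
#' @param mu baseline ADG in kg/day.
#' @param sex_effect additive male effect in kg/day.
#' @param year_effect_sd SD of the per-year fixed effects.
#' @param residual_sd residual SD in kg/day, calibrated so that the marginal
#'   phenotype SD is close to 0.353 under the other defaults.
#' @param year_base calendar year assigned to the founder generation.
#' @param seed integer seed; all generator randomness derives from it.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_founder_sires = 2, n_founder_dams = 50,
                       n_generations = 8, offspring_per_dam = 2,
                       sires_per_generation = 2,
                       max_dams_per_generation = 50,
                       chromosomes = default_chromosomes(),
                       snp_spacing_bp = 50000, cm_per_mb = 1.0,
                       maf_range = c(0.05, 0.5),
                       depression_effects = c(`2` = -0.2, `4` = -0.2,
                                              `10` = -0.2),
                       mu = 0.83, sex_effect = 0.15, year_effect_sd = 0.08,
                       residual_sd = 0.33, year_base = 1990, seed = 1) {
  stopifnot(n_founder_sires >= 1, n_founder_dams >= 1, n_generations >= 0,
            offspring_per_dam >= 1, sires_per_generation >= 1,
            nrow(chromosomes) >= 1, all(chromosomes$length_bp > 0),
            snp_spacing_bp > 0, cm_per_mb >= 0, residual_sd >= 0,
            all(is.finite(depression_effects)))
  structure(list(n_founder_sires = n_founder_sires,
                 n_founder_dams = n_founder_dams,
                 n_generations = n_generations,
                 offspring_per_dam = offspring_per_dam,
                 sires_per_generation = sires_per_generation,
                 max_dams_per_generation = max_dams_per_generation,
                 chromosomes = chromosomes,
                 snp_spacing_bp = snp_spacing_bp, cm_per_mb = cm_per_mb,
                 maf_range = maf_range,
                 depression_effects = depression_effects,
                 mu = mu, sex_effect = sex_effect,
                 year_effect_sd = year_effect_sd,
                 residual_sd = residual_sd, year_base = year_base,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Small preset for fast tests
#'
#' Three 10-Mb chromosomes (600 SNPs), 12 founder dams, 4 generations of 3
#' calves per dam: about 160 animals.
#'
#' @param ... overrides passed on to [sim_config()].
#' @return a \code{sim_config}.
#' @export
sim_config_tiny <- function(...) {
  chr <- data.frame(id = 1:3, length_bp = rep(1e7, 3), is_x = FALSE)
  defaults <- list(n_founder_dams = 12, n_generations = 4,
                   offspring_per_dam = 3, chromosomes = chr,
                   depression_effects = c(`2` = -0.2))
  args <- list(...)
  defaults[names(args)] <- args  # wholesale replacement (no list merging)
  do.call(sim_config, defaults)
}

#' Simulate a closed-line pedigree
#'
#' Founders are \code{n_founder_sires} bulls sharing one phantom sire (so
#' they are paternal half sibs) and \code{n_founder_dams} unrelated cows.
#' Each later generation draws a few sires from the previous generation's
#' males and mates them to the previous generation's females (capped at
#' \code{max_dams_per_generation}); each dam leaves
#' \code{offspring_per_dam} calves of random sex. Years of birth advance one
#' per generation. Fully deterministic given \code{cfg$seed}.
#'
#' @param cfg a [sim_config()].
#' @return list with \code{ped} (a [ped_table()], including the phantom
#'   sire) and \code{info} (data.frame \code{animal}, \code{sex},
#'   \code{year_of_birth}, \code{generation}; the phantom sire is excluded).
#' @export
simulate_pedigree <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  phantom <- "PHANTOM_S"
  sires0 <- sprintf("FS%02d", seq_len(cfg$n_founder_sires))
  dams0 <- sprintf("FD%03d", seq_len(cfg$n_founder_dams))
  animal <- c(phantom, sires0, dams0)
  sire <- c(NA, rep(phantom, length(sires0)), rep(NA, length(dams0)))
  dam <- rep(NA_character_, length(animal))
  sex <- c(rep("M", 1 + length(sires0)), rep("F", length(dams0)))
  gen <- rep(0L, length(animal))
  males <- sires0
  females <- dams0
  for (g in seq_len(cfg$n_generations)) {
    if (!length(males)) stop("population extinct: no males in generation ",
                             g - 1L)
    ns <- min(cfg$sires_per_generation, length(males))
    sires_g <- sample(males, ns)
    dams_g <- if (length(females) > cfg$max_dams_per_generation)
      sample(females, cfg$max_dams_per_generation) else females
    if (!length(dams_g)) stop("population extinct: no females in generation ",
                              g - 1L)
    new_ids <- character(0); new_sire <- character(0)
    new_dam <- character(0); new_sex <- character(0)
    k <- 0L
    for (d in dams_g) {
      for (o in seq_len(cfg$offspring_per_dam)) {
        k <- k + 1L
        new_ids <- c(new_ids, sprintf("G%d_%04d", g, k))
        new_sire <- c(new_sire, sample(sires_g, 1))
        new_dam <- c(new_dam, d)
        new_sex <- c(new_sex, if (stats::runif(1) < 0.5) "M" else "F")
      }
    }
    animal <- c(animal, new_ids)
    sire <- c(sire, new_sire)
    dam <- c(dam, new_dam)
    sex <- c(sex, new_sex)
    gen <- c(gen, rep(g, length(new_ids)))
    males <- new_ids[new_sex == "M"]
    females <- new_ids[new_sex == "F"]
  }
  ped <- ped_table(animal, sire, dam)
  keep <- animal != phantom
  info <- data.frame(animal = animal[keep], sex = sex[keep],
                     year_of_birth = cfg$year_base + gen[keep],
                     generation = gen[keep], stringsAsFactors = FALSE)
  list(ped = ped, info = info)
}

# --- haplotype mosaics -------------------------------------------------------
# a mosaic is list(breaks, labels): label labels[i] occupies
# (breaks[i], breaks[i+1]] with breaks[1] = 0 and breaks[last] = L

.new_founder_hap <- function(label, L) list(breaks = c(0, L), labels = label)

# recombine two mosaics of length L with crossovers at `xo` (sorted, within
# (0, L)), starting from hap `first` (1 or 2)
.recombine <- function(h1, h2, L, xo, first) {
  if (!length(xo)) return(if (first == 1L) h1 else h2)
  cuts <- c(0, xo, L)
  src <- rep(c(first, 3L - first), length.out = length(cuts) - 1L)
  breaks <- 0
  labels <- integer(0)
  for (s in seq_len(length(cuts) - 1L)) {
    a <- cuts[s]; b <- cuts[s + 1L]
    h <- if (src[s] == 1L) h1 else h2
    i0 <- findInterval(a, h$breaks, left.open = FALSE)  # segment containing (a, ...]
    i0 <- max(i0, 1L)
    i <- i0
    while (i <= length(h$labels) && h$breaks[i] < b) {
      end <- min(h$breaks[i + 1L], b)
      if (end > a) {
        if (length(labels) && labels[length(labels)] == h$labels[i]) {
          breaks[length(breaks)] <- end  # merge equal-label neighbors
        } else {
          labels <- c(labels, h$labels[i])
          breaks <- c(breaks, end)
        }
      }
      i <- i + 1L
    }
  }
  list(breaks = c(0, breaks[-1L]), labels = labels)
}

.meiosis <- function(h1, h2, L, cm_per_mb) {
  morgans <- L / 1e6 * cm_per_mb / 100
  n_xo <- stats::rpois(1, morgans)
  xo <- if (n_xo) sort(stats::runif(n_xo, 0, L)) else numeric(0)
  first <- sample(1:2, 1)
  .recombine(h1, h2, L, xo, first)
}

# fraction of (0, L] where the two mosaics carry the same label
.ibd_fraction <- function(h1, h2, L) {
  cuts <- sort(unique(c(h1$breaks, h2$breaks)))
  mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
  l1 <- h1$labels[findInterval(mids, h1$breaks, left.open = FALSE)]
  l2 <- h2$labels[findInterval(mids, h2$breaks, left.open = FALSE)]
  sum((cuts[-1] - cuts[-length(cuts)])[l1 == l2]) / L
}

#' Gene-drop founder haplotypes through a pedigree
#'
#' Every founder receives uniquely labeled haplotypes (two per chromosome;
#' one X for males). Meioses place crossovers by a Poisson process at
#' \code{cm_per_mb} (Haldane model, no interference). An animal's true IBD
#' fraction per chromosome is the fraction of base pairs where its two
#' haplotype labels coincide (\code{NA} on the X for males). SNP genotypes
#' are read off the mosaics: founder haplotypes carry biallelic alleles drawn
#' at per-SNP frequencies from \code{maf_range}, so chance homozygosity (IBS)
#' arises alongside true IBD. An unknown parent transmits a fresh founder
#' haplotype.
#'
#' @param ped a [ped_table()] (will be sorted).
#' @param cfg a [sim_config()]; an \code{info} data.frame with a \code{sex}
#'   column per animal is required for X inheritance and must be supplied via
#'   \code{info} when the map includes an X chromosome.
#' @param info data.frame with \code{animal} and \code{sex} (phantom/pedigree
#'   padding animals absent from \code{info} default to male).
#' @return list with \code{genotypes} ([genotype_matrix()] over the animals
#'   in \code{info}), \code{map} ([snp_map()]), \code{truth} (data.frame:
#'   \code{animal}, one \code{ibd_chr<c>} column per chromosome, plus
#'   \code{ibd_genome}, length-weighted over diploid chromosomes).
#' @export
gene_drop <- function(ped, cfg = sim_config(), info = NULL) {
  set.seed(cfg$seed + 1L)
  ped <- topological_sort(ped)
  id <- ped$animal
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  chr <- cfg$chromosomes
  sex <- stats::setNames(rep("M", length(id)), id)
  if (!is.null(info)) sex[info$animal] <- info$sex
  # map
  map_list <- lapply(seq_len(nrow(chr)), function(k) {
    pos <- seq(cfg$snp_spacing_bp / 2, chr$length_bp[k],
               by = cfg$snp_spacing_bp)
    data.frame(snp_id = sprintf("snp%d_%d", chr$id[k], seq_along(pos)),
               chromosome = chr$id[k], position_bp = pos)
  })
  map_df <- do.call(rbind, map_list)
  map <- snp_map(map_df$snp_id, map_df$chromosome, map_df$position_bp)
  n_snp_per_chr <- vapply(map_list, nrow, integer(1))
  # per chromosome: list over animals of list(h1, h2) (h2 NULL on male X);
  # founder haplotype labels are unique within a chromosome
  haps <- vector("list", nrow(chr))
  n_labels <- integer(nrow(chr))
  ibd <- matrix(NA_real_, length(id), nrow(chr),
                dimnames = list(id, chr$id))
  for (k in seq_len(nrow(chr))) {
    L <- chr$length_bp[k]
    is_x <- chr$is_x[k]
    label_counter <- 0L
    new_label <- function() { label_counter <<- label_counter + 1L; label_counter }
    hk <- vector("list", length(id))
    for (i in seq_len(length(id))) {
      s <- si[i]; d <- di[i]
      male <- sex[id[i]] == "M"
      founder_side <- function() .new_founder_hap(new_label(), L)
      if (is_x && male) {
        # single maternally inherited X
        h <- if (is.na(d)) founder_side()
        else .meiosis(hk[[d]]$h1, hk[[d]]$h2, L, cfg$cm_per_mb)
        hk[[i]] <- list(h1 = h, h2 = NULL)
        ibd[i, k] <- NA_real_
      } else if (is_x && !male) {
        hm <- if (is.na(d)) founder_side()
        else .meiosis(hk[[d]]$h1, hk[[d]]$h2, L, cfg$cm_per_mb)
        hp <- if (is.na(s)) founder_side() else hk[[s]]$h1  # sire X unchanged
        hk[[i]] <- list(h1 = hm, h2 = hp)
        ibd[i, k] <- .ibd_fraction(hm, hp, L)
      } else {
        hm <- if (is.na(d)) founder_side()
        else .meiosis(hk[[d]]$h1, hk[[d]]$h2, L, cfg$cm_per_mb)
        hp <- if (is.na(s)) founder_side()
        else .meiosis(hk[[s]]$h1, hk[[s]]$h2, L, cfg$cm_per_mb)
        hk[[i]] <- list(h1 = hm, h2 = hp)
        ibd[i, k] <- .ibd_fraction(hm, hp, L)
      }
    }
    haps[[k]] <- hk
    n_labels[k] <- label_counter
  }
  out_ids <- if (is.null(info)) id else info$animal
  calls <- matrix(NA_integer_, length(out_ids), nrow(map))
  col_off <- c(0L, cumsum(n_snp_per_chr))
  for (k in seq_len(nrow(chr))) {
    pos <- map_list[[k]]$position_bp
    cols <- col_off[k] + seq_len(n_snp_per_chr[k])
    # founder allele assignment for this chromosome: label x SNP
    p_by_snp <- stats::runif(n_snp_per_chr[k], cfg$maf_range[1],
                             cfg$maf_range[2])
    allele <- matrix(stats::rbinom(n_labels[k] * n_snp_per_chr[k], 1,
                                   rep(p_by_snp, each = n_labels[k])),
                     nrow = n_labels[k])
    snp_idx <- seq_len(n_snp_per_chr[k])
    for (a in seq_along(out_ids)) {
      i <- match(out_ids[a], id)
      hp <- haps[[k]][[i]]
      lab1 <- hp$h1$labels[findInterval(pos, hp$h1$breaks, left.open = TRUE)]
      a1 <- allele[cbind(lab1, snp_idx)]
      if (is.null(hp$h2)) {
        calls[a, cols] <- 2L * a1  # male X recorded homozygous
      } else {
        lab2 <- hp$h2$labels[findInterval(pos, hp$h2$breaks, left.open = TRUE)]
        a2 <- allele[cbind(lab2, snp_idx)]
        calls[a, cols] <- a1 + a2
      }
    }
  }
  gm <- genotype_matrix(calls, out_ids, map)
  wt <- chr$length_bp
  ibd_out <- ibd[out_ids, , drop = FALSE]
  num <- rowSums(sweep(ibd_out, 2, wt, "*"), na.rm = TRUE)
  den <- as.vector((!is.na(ibd_out)) %*% wt)
  genome <- ifelse(den > 0, num / den, NA_real_)
  truth <- data.frame(animal = out_ids, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(chr)))
    truth[[paste0("ibd_chr", chr$id[k])]] <- ibd_out[, k]
  truth$ibd_genome <- genome
  list(genotypes = gm, map = map, truth = truth)
}

#' Simulate growth phenotypes with chromosome-specific depression
#'
#' \code{adg_raw = mu + sex_effect * [male] + year_effect[year] + sum_c b_c *
#' IBD_c + N(0, residual_sd)}. Year effects are drawn once from
#' \code{N(0, year_effect_sd)} (deterministic given the seed) and returned as
#' an attribute. Chromosomes with no depression effect contribute nothing;
#' male X IBD (missing) contributes nothing.
#'
#' @param truth truth table from [gene_drop()].
#' @param info data.frame with \code{animal}, \code{sex},
#'   \code{year_of_birth}.
#' @param cfg a [sim_config()].
#' @return phenotype data.frame (\code{animal}, \code{sex},
#'   \code{year_of_birth}, \code{adg_raw}) with attributes
#'   \code{year_effects} and \code{genetic_value}.
#' @export
simulate_phenotype <- function(truth, info, cfg = sim_config()) {
  set.seed(cfg$seed + 2L)
  idx <- match(info$animal, truth$animal)
  stopifnot(!anyNA(idx))
  years <- sort(unique(info$year_of_birth))
  year_eff <- stats::setNames(stats::rnorm(length(years), 0,
                                           cfg$year_effect_sd), years)
  g <- numeric(nrow(info))
  for (ch in names(cfg$depression_effects)) {
    col <- paste0("ibd_chr", ch)
    if (!col %in% names(truth)) next
    v <- truth[[col]][idx]
    v[is.na(v)] <- 0  # male X: no contribution
    g <- g + cfg$depression_effects[[ch]] * v
  }
  adg <- cfg$mu + cfg$sex_effect * (info$sex == "M") +
    year_eff[as.character(info$year_of_birth)] + g +
    stats::rnorm(nrow(info), 0, cfg$residual_sd)
  out <- data.frame(animal = info$animal, sex = info$sex,
                    year_of_birth = info$year_of_birth,
                    adg_raw = unname(adg), stringsAsFactors = FALSE)
  attr(out, "year_effects") <- year_eff
  attr(out, "genetic_value") <- g
  out
}

#' Simulate a complete study and optionally write it to disk
#'
#' Runs [simulate_pedigree()], [gene_drop()] and [simulate_phenotype()] and,
#' when \code{dir} is given, writes PLINK PED/MAP and BED/BIM/FAM files, a
#' pedigree CSV, a phenotype CSV and the truth table CSV. Identical seeds
#' give byte-identical files.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created); \code{NULL} skips writing.
#' @return list with \code{ped}, \code{info}, \code{genotypes}, \code{map},
#'   \code{truth}, \code{phenos}, \code{dir}.
#' @export
end_to_end_fixture <- function(cfg = sim_config(), dir = NULL) {
  sim <- simulate_pedigree(cfg)
  gd <- gene_drop(sim$ped, cfg, info = sim$info)
  phenos <- simulate_phenotype(gd$truth, sim$info, cfg)
  out <- list(ped = sim$ped, info = sim$info, genotypes = gd$genotypes,
              map = gd$map, truth = gd$truth, phenos = phenos, dir = dir)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sexes <- stats::setNames(sim$info$sex, sim$info$animal)
    write_plink(gd$genotypes, gd$map, file.path(dir, "study"),
                dialect = "ped_map", sexes = sexes)
    write_plink(gd$genotypes, gd$map, file.path(dir, "study"),
                dialect = "bed_bim_fam", sexes = sexes)
    write_pedigree(sim$ped, file.path(dir, "pedigree.csv"))
    write_phenotypes(phenos, file.path(dir, "phenotypes.csv"))
    utils::write.csv(gd$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE, quote = FALSE, na = "")
  }
  out
}
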
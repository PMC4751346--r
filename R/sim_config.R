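#' Configuration of the breeding-program simulator
#'
#' Collects every parameter of the synthetic breeding program: genome and
#' marker map, trait architecture sizes, founder and drift settings, the
#' polycross scheme, and the labelled generation schedule for the two
#' lineages.  Defaults mirror a perennial ryegrass recurrent-selection
#' program: 7 chromosomes totalling 8 Morgans, 1670 mapped markers, a
#' polycross of ~500 plants from 5 families, ~100 mother-plants selected per
#' generation whose half-sib progeny are evaluated in 4 replicate sward
#' plots, an Intermediate lineage observed at F11-F14 and a Late lineage
#' observed at F5.
#'
#' @param n_chromosomes number of chromosomes (default 7).
#' @param chromosome_length length of each chromosome in Morgans (recycled;
#'   default 8/7, i.e. an 8-Morgan genome).
#' @param n_markers total mapped markers, evenly spaced (default 1670).
#' @param n_qtl QTL per trait, positions uniform on the map (default 100).
#' @param founder_count individuals founding each lineage (default 10).
#' @param effective_size population size of the drift burn-in that creates
#'   map-consistent background LD (default 200).
#' @param burnin_generations random-mating generations of burn-in
#'   (default 60).
#' @param polycross_size parents per polycross (default 500; the program
#'   uses 400-600).
#' @param n_families half-sib families selected to parent the next cycle
#'   (default 5; the program uses 4-6).
#' @param n_mothers mother-plants selected per generation (the program
#'   selects roughly 100; default 120 so the largest genotyped cohort of the
#'   default schedule is covered).
#' @param progeny_per_family half-sib progeny simulated per mother for the
#'   sward phenotype (default 50).
#' @param n_plots replicate sward plots per family (default 4).
#' @param trait_h2 named numeric vector mapping trait name to target
#'   plot-level broad-sense heritability in \[0, 1); defaults to the 11
#'   yield, persistency and quality traits of the study.
#' @param index_trait trait whose family means drive between-cycle family
#'   selection (default first trait).
#' @param generations data.frame with columns `lineage`, `label`,
#'   `n_genotyped` giving, in breeding order per lineage, the labelled
#'   generations to emit and how many of their mother-plants are genotyped.
#'   The default mirrors the study: Intermediate F11/F12/F13/F14 with
#'   119/86/54/100 genotyped and Late F5 with 105.
#' @param pre_label_cycles unlabelled selection cycles run between lineage
#'   founding and the first labelled generation (default 1).
#' @param seed integer random seed used by [simulate_program()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 7L,
                       chromosome_length = 8 / 7,
                       n_markers = 1670L,
                       n_qtl = 100L,
                       founder_count = 10L,
                       effective_size = 200L,
                       burnin_generations = 60L,
                       polycross_size = 500L,
                       n_families = 5L,
                       n_mothers = 120L,
                       progeny_per_family = 50L,
                       n_plots = 4L,
                       trait_h2 = default_trait_h2(),
                       index_trait = names(trait_h2)[1L],
                       generations = default_generation_schedule(),
                       pre_label_cycles = 1L,
                       seed = 1L) {
  chromosome_length <- rep_len(as.numeric(chromosome_length), n_chromosomes)
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = chromosome_length,
              n_markers = as.integer(n_markers),
              n_qtl = as.integer(n_qtl),
              founder_count = as.integer(founder_count),
              effective_size = as.integer(effective_size),
              burnin_generations = as.integer(burnin_generations),
              polycross_size = as.integer(polycross_size),
              n_families = as.integer(n_families),
              n_mothers = as.integer(n_mothers),
              progeny_per_family = as.integer(progeny_per_family),
              n_plots = as.integer(n_plots),
              trait_h2 = trait_h2,
              index_trait = index_trait,
              generations = as.data.frame(generations),
              pre_label_cycles = as.integer(pre_label_cycles),
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  counts <- c("n_chromosomes", "n_markers", "n_qtl", "founder_count",
              "effective_size", "polycross_size", "n_families", "n_mothers",
              "progeny_per_family", "n_plots")
  for (f in counts)
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("sim_config: '", f, "' must be a positive count")
  if (cfg$burnin_generations < 0L || cfg$pre_label_cycles < 0L)
    stop("sim_config: burn-in generations and pre-label cycles must be >= 0")
  if (any(cfg$chromosome_length <= 0))
    stop("sim_config: chromosome lengths must be > 0")
  if (is.null(names(cfg$trait_h2)) || any(!nzchar(names(cfg$trait_h2))))
    stop("sim_config: trait_h2 must be a named vector")
  if (any(cfg$trait_h2 < 0 | cfg$trait_h2 >= 1))
    stop("sim_config: trait_h2 values must lie in [0, 1)")
  if (!cfg$index_trait %in% names(cfg$trait_h2))
    stop("sim_config: index_trait '", cfg$index_trait, "' has no heritability")
  sched <- cfg$generations
  if (!all(c("lineage", "label", "n_genotyped") %in% names(sched)))
    stop("sim_config: generations needs columns lineage, label, n_genotyped")
  if (anyDuplicated(sched$label))
    stop("sim_config: generation labels must be unique")
  if (any(sched$n_genotyped < 1L) || any(sched$n_genotyped > cfg$n_mothers))
    stop("sim_config: n_genotyped must be in 1..n_mothers")
  if (cfg$n_mothers > cfg$polycross_size)
    stop("sim_config: n_mothers cannot exceed polycross_size")
  if (cfg$n_families > cfg$n_mothers)
    stop("sim_config: n_families cannot exceed n_mothers")
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_trait_h2 <- function() {
  c(totaly7c_yr1 = 0.40, totaly7c_yr2 = 0.34, conscuty_yr1 = 0.17,
    conscuty_yr2 = 0.17, vegyld_yr1 = 0.44, vegyld_yr2 = 0.34,
    gcscore_yr1 = 0.19, gcscore_yr2 = 0.12, dmd = 0.59, n = 0.35,
    wsc = 0.41)
}

#' @rdname sim_config
#' @export
default_generation_schedule <- function() {
  data.frame(
    lineage = c("Intermediate", "Intermediate", "Intermediate", "Intermediate",
                "Late"),
    label = c("F11", "F12", "F13", "F14", "F5"),
    n_genotyped = c(119L, 86L, 54L, 100L, 105L),
    stringsAsFactors = FALSE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Breeding-program simulation config\n")
  cat(sprintf("  genome: %d chromosomes, %.2f Morgans, %d markers, %d QTL/trait\n",
              x$n_chromosomes, sum(x$chromosome_length), x$n_markers, x$n_qtl))
  cat(sprintf("  founding: %d founders from burn-in (Ne = %d, %d generations)\n",
              x$founder_count, x$effective_size, x$burnin_generations))
  cat(sprintf("  cycle: polycross of %d from %d families; %d mothers; %d progeny x %d plots\n",
              x$polycross_size, x$n_families, x$n_mothers,
              x$progeny_per_family, x$n_plots))
  cat(sprintf("  traits: %d (index: %s); seed %d\n",
              length(x$trait_h2), x$index_trait, x$seed))
  sched <- x$generations
  cat("  schedule:",
      paste(sprintf("%s:%s(%d)", sched$lineage, sched$label, sched$n_genotyped),
            collapse = " "), "\n")
  invisible(x)
}
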
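#' Simulation configuration
#'
#' Builds and validates the parameter set for the whole-genome-duplication
#' simulator. The defaults describe a desk-scale caricature of the real
#' comparison this package was designed around: a diploid genome of 10
#' chromosomes carrying a genetic map of ~100 cM each, and a derived genome
#' produced by one whole-genome duplication followed by fractionation and
#' segmental rearrangement. Roughly half of each chromosome is pericentromeric,
#' with recombination suppressed ten-fold there.
#'
#' @param n_chromosomes Number of ancestor chromosomes (>= 1).
#' @param genes_per_chromosome Genes placed on each ancestor chromosome (>= 1).
#' @param mean_gene_spacing Mean intergenic gap, bp (exponentially distributed).
#' @param mean_gene_length Mean gene length, bp.
#' @param map_length_per_chromosome Genetic length of each linkage group, cM.
#' @param pericentromere_fraction Fraction of each chromosome's length occupied
#'   by the central pericentromeric interval, in `[0, 1]`.
#' @param pericentromere_recombination_factor Multiplier in `(0, 1]` applied to
#'   recombination density inside the pericentromere (1 = no suppression).
#' @param fractionation_rate Probability that each duplicated gene copy is
#'   deleted after the duplication, independently per copy.
#' @param n_rearrangements Number of segmental moves applied to the derived
#'   genome.
#' @param mean_segment_genes Mean length (genes) of a moved segment; segment
#'   lengths are `1 + Geometric`.
#' @param inversion_probability Probability a moved segment is inverted.
#' @param divergence Substitution-distance proxy in `[0, 1)` driving simulated
#'   percent identity, bit scores and E-values.
#' @param spurious_rate Mean number of weak decoy hits added per query
#'   (Poisson).
#' @param evalue_log_sd Standard deviation of the log10 noise added to
#'   simulated E-values.
#' @param marker_fraction Fraction of ancestor genes carrying genetic-map
#'   positions.
#' @param chromosome_length_bp Optional fixed ancestor chromosome length; when
#'   `NULL` the length is taken just past the last gene. Supplying a length the
#'   simulated genes do not fit in is an error at simulation time.
#' @param seed Integer seed; a fixed seed makes every simulator output
#'   byte-identical.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 50, seed = 7)
#' cfg$map_length_per_chromosome
#' @export
sim_config <- function(n_chromosomes = 10,
                       genes_per_chromosome = 500,
                       mean_gene_spacing = 20000,
                       mean_gene_length = 1000,
                       map_length_per_chromosome = 100,
                       pericentromere_fraction = 0.5,
                       pericentromere_recombination_factor = 0.1,
                       fractionation_rate = 0.1,
                       n_rearrangements = 20,
                       mean_segment_genes = 100,
                       inversion_probability = 0.5,
                       divergence = 0.1,
                       spurious_rate = 0,
                       evalue_log_sd = 2,
                       marker_fraction = 0.1,
                       chromosome_length_bp = NULL,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    mean_gene_spacing = as.numeric(mean_gene_spacing),
    mean_gene_length = as.numeric(mean_gene_length),
    map_length_per_chromosome = as.numeric(map_length_per_chromosome),
    pericentromere_fraction = as.numeric(pericentromere_fraction),
    pericentromere_recombination_factor =
      as.numeric(pericentromere_recombination_factor),
    fractionation_rate = as.numeric(fractionation_rate),
    n_rearrangements = as.integer(n_rearrangements),
    mean_segment_genes = as.numeric(mean_segment_genes),
    inversion_probability = as.numeric(inversion_probability),
    divergence = as.numeric(divergence),
    spurious_rate = as.numeric(spurious_rate),
    evalue_log_sd = as.numeric(evalue_log_sd),
    marker_fraction = as.numeric(marker_fraction),
    chromosome_length_bp = if (is.null(chromosome_length_bp)) NULL
                           else as.numeric(chromosome_length_bp),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_if <- function(bad, msg) if (bad) stop(msg, call. = FALSE)
  stop_if(cfg$n_chromosomes < 1L, "n_chromosomes must be >= 1")
  stop_if(cfg$genes_per_chromosome < 1L, "genes_per_chromosome must be >= 1")
  stop_if(cfg$mean_gene_spacing <= 0, "mean_gene_spacing must be positive")
  stop_if(cfg$mean_gene_length <= 0, "mean_gene_length must be positive")
  stop_if(cfg$map_length_per_chromosome <= 0,
          "map_length_per_chromosome must be positive")
  for (p in c("pericentromere_fraction", "fractionation_rate",
              "inversion_probability", "marker_fraction")) {
    stop_if(cfg[[p]] < 0 || cfg[[p]] > 1,
            sprintf("%s must be in [0, 1]", p))
  }
  stop_if(cfg$pericentromere_recombination_factor <= 0 ||
            cfg$pericentromere_recombination_factor > 1,
          "pericentromere_recombination_factor must be in (0, 1]")
  stop_if(cfg$divergence < 0 || cfg$divergence >= 1,
          "divergence must be in [0, 1)")
  stop_if(cfg$n_rearrangements < 0L, "n_rearrangements must be >= 0")
  stop_if(cfg$mean_segment_genes < 1, "mean_segment_genes must be >= 1")
  stop_if(cfg$spurious_rate < 0, "spurious_rate must be >= 0")
  stop_if(cfg$evalue_log_sd < 0, "evalue_log_sd must be >= 0")
  stop_if(is.na(cfg$seed), "seed must be an integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome : %d chromosomes x %d genes (spacing ~%g bp)\n",
              x$n_chromosomes, x$genes_per_chromosome, x$mean_gene_spacing))
  cat(sprintf("  map    : %g cM per linkage group, %g%% of genes as markers\n",
              x$map_length_per_chromosome, 100 * x$marker_fraction))
  cat(sprintf("  peri   : fraction %g, recombination factor %g\n",
              x$pericentromere_fraction,
              x$pericentromere_recombination_factor))
  cat(sprintf(
    "  history: WGD + fractionation %g, %d rearrangements (~%g genes, P(inv)=%g)\n",
    x$fractionation_rate, x$n_rearrangements, x$mean_segment_genes,
    x$inversion_probability))
  cat(sprintf("  hits   : divergence %g, spurious rate %g, seed %d\n",
              x$divergence, x$spurious_rate, x$seed))
  invisible(x)
}
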
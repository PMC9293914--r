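#' @include AllClasses.R simulate.R
NULL

#' Configuration of the bulk RNA-seq simulator
#'
#' Describes a bulk expression experiment over molecular subtypes: a shared
#' Gamma baseline mean profile, per-subtype fold effects on subtype-defining
#' gene blocks, lognormal library sizes and negative-binomial counts.
#'
#' @slot nGenes integer(1).
#' @slot subtypes named list; per subtype a list with \code{genes}
#'   (character ids of its defining genes) and \code{fold} (> 0).
#' @slot samplesPerSubtype integer(1) samples drawn per subtype.
#' @slot librarySizeMeanlog,librarySizeSdlog lognormal library-size
#'   parameters.
#' @slot nbDispersion numeric(1) > 0, NB size parameter.
#' @slot seed integer(1).
#'
#' @seealso [bulkConfig()], [simulateBulk()]
#' @export
setClass("BulkSimConfig",
  representation(
    nGenes             = "integer",
    subtypes           = "list",
    samplesPerSubtype  = "integer",
    librarySizeMeanlog = "numeric",
    librarySizeSdlog   = "numeric",
    nbDispersion       = "numeric",
    seed               = "integer"
  )
)

setValidity("BulkSimConfig", function(object) {
  msg <- character()
  if (length(object@subtypes) < 1L || is.null(names(object@subtypes)) ||
      anyDuplicated(names(object@subtypes)))
    msg <- c(msg, "'subtypes' must be a uniquely named list")
  universe <- sprintf("G%05d", seq_len(object@nGenes))
  for (s in names(object@subtypes)) {
    st <- object@subtypes[[s]]
    if (!all(c("genes", "fold") %in% names(st)) || st$fold <= 0)
      msg <- c(msg, sprintf("subtype '%s' needs genes and positive fold", s))
    else if (!all(st$genes %in% universe))
      msg <- c(msg, sprintf("subtype '%s' uses genes outside the universe", s))
  }
  if (object@samplesPerSubtype < 1L)
    msg <- c(msg, "'samplesPerSubtype' must be >= 1")
  if (object@nbDispersion <= 0) msg <- c(msg, "'nbDispersion' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a bulk simulator configuration
#'
#' Defaults give two subtypes ("basal", "luminal"), each defined by a
#' 50-gene block at 4-fold elevation, with 10 samples per subtype — a
#' strong-signal design under which nearest-centroid subtyping should
#' recover every label.
#'
#' @param nGenes number of genes (default 1000).
#' @param subtypes named list of subtype descriptors (\code{genes},
#'   \code{fold}); default two 50-gene programs at fold 4.
#' @param samplesPerSubtype samples per subtype (default 10).
#' @param librarySizeMeanlog,librarySizeSdlog lognormal library size
#'   (default meanlog log(1e6), sdlog 0.2).
#' @param nbDispersion NB size parameter (default 10).
#' @param seed RNG seed.
#' @return A validated [BulkSimConfig-class].
#' @export
bulkConfig <- function(nGenes = 1000L, subtypes = NULL,
                       samplesPerSubtype = 10L,
                       librarySizeMeanlog = log(1e6),
                       librarySizeSdlog = 0.2,
                       nbDispersion = 10, seed = 1L) {
  nGenes <- as.integer(nGenes)
  if (is.null(subtypes)) {
    ids <- sprintf("G%05d", seq_len(nGenes))
    len <- min(50L, max(1L, nGenes %/% 4L))
    subtypes <- list(
      basal   = list(genes = ids[seq_len(len)], fold = 4),
      luminal = list(genes = ids[seq.int(len + 1L, length.out = len)],
                     fold = 4))
  }
  new("BulkSimConfig", nGenes = nGenes, subtypes = subtypes,
      samplesPerSubtype = as.integer(samplesPerSubtype),
      librarySizeMeanlog = as.numeric(librarySizeMeanlog),
      librarySizeSdlog = as.numeric(librarySizeSdlog),
      nbDispersion = as.numeric(nbDispersion), seed = as.integer(seed))
}

#' Simulate bulk expression counts over molecular subtypes
#'
#' Per-sample counts are NB(mean = librarySize * lambda * fold, size =
#' nbDispersion) where lambda is a shared Gamma baseline normalized within
#' each subtype and fold elevates the subtype's defining genes.
#' Deterministic given the config seed.
#'
#' @param config a [BulkSimConfig-class].
#' @return list with \code{counts} (integer genes x samples matrix),
#'   \code{truth} (named character vector, subtype per sample) and
#'   \code{meanProfiles} (genes x subtypes matrix of generating relative
#'   means, each column summing to 1).
#' @examples
#' sim <- simulateBulk(bulkConfig(seed = 3))
#' table(sim$truth)
#' @export
simulateBulk <- function(config) {
  stopifnot(is(config, "BulkSimConfig"))
  validObject(config)
  withr::with_seed(config@seed, {
    G <- config@nGenes
    geneIds <- sprintf("G%05d", seq_len(G))
    base <- rgamma(G, shape = 0.8, scale = 1)
    profiles <- vapply(names(config@subtypes), function(s) {
      st <- config@subtypes[[s]]
      l <- base
      l[match(st$genes, geneIds)] <- l[match(st$genes, geneIds)] * st$fold
      l / sum(l)
    }, numeric(G))
    rownames(profiles) <- geneIds

    n <- config@samplesPerSubtype
    truth <- rep(names(config@subtypes), each = n)
    sampleIds <- sprintf("%s_s%02d", truth,
                         rep(seq_len(n), length(config@subtypes)))
    libsize <- rlnorm(length(truth), config@librarySizeMeanlog,
                      config@librarySizeSdlog)
    mu <- profiles[, truth, drop = FALSE] *
      rep(libsize, each = G)
    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = config@nbDispersion), nrow = G,
                     dimnames = list(geneIds, sampleIds))
    list(counts = counts, truth = setNames(truth, sampleIds),
         meanProfiles = profiles)
  })
}

#' Build a centroid model from generating mean profiles
#'
#' Converts per-subtype relative mean profiles (columns summing to 1, as
#' returned by [simulateBulk()]) into centroids on the scale of
#' [bulkPrepare()] output: log2(1 + scale * lambda), median-centered per
#' gene across subtypes.
#'
#' @param meanProfiles genes x subtypes matrix of relative means.
#' @param scale pseudo library size before the log (default 1e6).
#' @return A [CentroidModel-class].
#' @export
makeCentroidModel <- function(meanProfiles, scale = 1e6) {
  m <- log2(1 + scale * as.matrix(meanProfiles))
  m <- m - apply(m, 1L, stats::median)
  centroidModel(m)
}
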
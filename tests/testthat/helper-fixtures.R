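## Shared fixtures: all synthetic, built in code at test time.

## A scan whose spectra all come from one phenotype template.
singleTypeScan <- function(phenotype, nSpectra = 100, seed = 1,
                           lowSnrFraction = 0, noiseLevel = 1) {
    recipe <- lesionRecipe("SK", nSpectra = nSpectra,
                           typeMix = stats::setNames(1, phenotype),
                           lowSnrFraction = lowSnrFraction,
                           noiseLevel = noiseLevel, seed = seed)
    generateLesion(recipe,
                   templates = stats::setNames(
                       list(composeTemplate(phenotype)), phenotype))
}

## Smoothed+normalized features of a noise-free template.
templateFeatures <- function(phenotype) {
    sp <- composeTemplate(phenotype)
    extractFeatures(normalizeSpectra(smoothSpectra(sp, 40)))
}

## Features and truth labels for n spectra per phenotype at default noise.
labeledFeatureSet <- function(nPerClass, seed) {
    types <- c(SK = "SK_TYPE", CM = "CM_TYPE", NEVUS = "NEVUS_TYPE",
               BACKGROUND = "UNINFORMATIVE")
    feats <- do.call(rbind, lapply(seq_along(types), function(i) {
        scan <- singleTypeScan(names(types)[i], nPerClass, seed + i)
        extractFeatures(normalizeSpectra(smoothSpectra(scan, 40)))
    }))
    list(features = feats,
         labels = rep(unname(types), each = nPerClass))
}

## Exhaustive nonnegative grid-search oracle for least-squares unmixing:
## enumerates every weight combination on a regular grid and returns the
## minimizer of ||y - B w||^2.  Independent of the NNLS code path.
gridSearchUnmix <- function(y, B, step = 0.01, upper = 0.25) {
    vals <- seq(0, upper, by = step)
    k <- ncol(B)
    W <- as.matrix(expand.grid(rep(list(vals), k)))
    G <- crossprod(B)                 # k x k Gram matrix
    b <- crossprod(B, y)              # k x 1
    obj <- rowSums((W %*% G) * W) - 2 * as.numeric(W %*% b)
    W[which.min(obj), ]
}
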
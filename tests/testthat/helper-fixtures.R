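## Small in-code fixtures shared across test files.

## A tiny two-client federation with 32x32 images (fast to generate).
tinySpec <- function(seed = 11, nClasses = c(3, 2), samplesPerClass = 2,
                     ...) {
  federationSpec(nClasses = nClasses, samplesPerClass = samplesPerClass,
                 height = 32, width = 32, noiseSd = 2, masterSeed = seed, ...)
}

tinyFederation <- function(seed = 11, ...) generateFederation(tinySpec(seed, ...))

## A client built directly from given images/labels.
makeClient <- function(images, labels, id = "c1", orientation = "vertical") {
  new("VeinClient", clientId = id, images = images, labels = labels,
      orientation = orientation)
}

## Random unit-column prototype set owned by `client`.
makePrototypes <- function(d, labels, client = "other", seed = 1,
                           nSamples = 2) {
  vec <- fedvein:::withSeed(seed,
    fedvein:::l2NormalizeCols(matrix(rnorm(d * length(labels)), d,
                                     length(labels))))
  new("PrototypeSet", vectors = vec,
      ownership = data.frame(client_id = client, class_label = labels,
                             n_samples = nSamples,
                             stringsAsFactors = FALSE))
}

## Independent plain log-sum-exp cross-entropy oracle over a logit matrix.
ceOracle <- function(logits, targets) {
  mean(vapply(seq_len(nrow(logits)), function(i) {
    l <- logits[i, ]
    log(sum(exp(l - max(l)))) + max(l) - l[targets[i]]
  }, numeric(1)))
}

## Brute-force EER oracle: dense threshold grid, minimize |FAR - FRR|.
eerOracle <- function(gen, imp, nGrid = 20001) {
  thr <- seq(min(gen, imp) - 1e-6, max(gen, imp) + 1e-6,
             length.out = nGrid)
  far <- vapply(thr, function(t) 100 * mean(imp >= t), numeric(1))
  frr <- vapply(thr, function(t) 100 * mean(gen < t), numeric(1))
  i <- which.min(abs(far - frr))
  (far[i] + frr[i]) / 2
}

## Brute-force TAR@FAR oracle: enumerate every distinct operating point of
## the empirical step functions (scores, midpoints between scores, and one
## point beyond the maximum) and take the first with FAR within budget.
tarOracle <- function(gen, imp, farTarget = 0.01) {
  s <- sort(unique(c(gen, imp)))
  thr <- sort(c(s, s[-1] - diff(s) / 2, max(s) + 1))
  far <- vapply(thr, function(t) 100 * mean(imp >= t), numeric(1))
  t0 <- thr[which(far <= farTarget * 100)[1]]
  100 - 100 * mean(gen < t0)
}

scoresOf <- function(gen, imp) new("VerificationScores", genuine = gen,
                                   impostor = imp)
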
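#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Metropolis sampler for the pairwise spin model with energy
//   E(sigma) = -beta * sum_{i,j} C_ij sigma_i sigma_j   (ordered double sum)
// so flipping spin i changes the energy by dE = 4 * beta * sigma_i * h_i
// with the local field h_i = sum_{j != i} C_ij sigma_j. beta is already
// inside E, hence the acceptance probability is exp(-dE).
//
// Local fields are cached and updated incrementally on every accepted
// flip; every checkInterval attempts they are recomputed from scratch and
// the largest deviation is reported (energy-bookkeeping diagnostic).
//
// Uses R's RNG so runs are reproducible via set.seed().

// [[Rcpp::export]]
List cpp_metropolis(NumericMatrix C, double beta, int nSamples,
                    double burnInAttempts, int storeInterval,
                    double checkInterval) {
    const int N = C.nrow();
    if (C.ncol() != N) stop("C must be square");
    for (int i = 0; i < N; ++i)
        if (C(i, i) != 0.0) stop("C must have a zero diagonal");

    // sparse adjacency (skips zero couplings; dense matrices fall through
    // to full rows)
    std::vector<std::vector<int> > nb(N);
    std::vector<std::vector<double> > wt(N);
    for (int i = 0; i < N; ++i) {
        for (int j = 0; j < N; ++j) {
            double w = C(i, j);
            if (w != 0.0 && j != i) {
                nb[i].push_back(j);
                wt[i].push_back(w);
            }
        }
    }

    RNGScope scope;
    std::vector<double> sigma(N);
    for (int i = 0; i < N; ++i)
        sigma[i] = (unif_rand() < 0.5) ? -1.0 : 1.0;

    std::vector<double> h(N, 0.0);
    for (int i = 0; i < N; ++i) {
        double hi = 0.0;
        for (size_t q = 0; q < nb[i].size(); ++q)
            hi += wt[i][q] * sigma[nb[i][q]];
        h[i] = hi;
    }

    IntegerMatrix conf(nSamples, N);
    NumericVector M(nSamples);
    double maxFieldErr = 0.0;
    long long burn = (long long) burnInAttempts;
    long long total = burn + (long long) nSamples * (long long) storeInterval;
    long long sinceCheck = 0;
    int stored = 0;

    for (long long t = 0; t < total; ++t) {
        int i = (int) (unif_rand() * N);
        if (i >= N) i = N - 1;
        double dE = 4.0 * beta * sigma[i] * h[i];
        if (dE < 0.0 || unif_rand() < std::exp(-dE)) {
            sigma[i] = -sigma[i];
            double twoS = 2.0 * sigma[i];
            const std::vector<int>& nbi = nb[i];
            const std::vector<double>& wti = wt[i];
            for (size_t q = 0; q < nbi.size(); ++q)
                h[nbi[q]] += twoS * wti[q];
        }
        if (checkInterval > 0 && ++sinceCheck >= (long long) checkInterval) {
            sinceCheck = 0;
            for (int a = 0; a < N; ++a) {
                double ha = 0.0;
                for (size_t q = 0; q < nb[a].size(); ++q)
                    ha += wt[a][q] * sigma[nb[a][q]];
                double err = std::fabs(ha - h[a]);
                if (err > maxFieldErr) maxFieldErr = err;
                h[a] = ha;
            }
        }
        if (t >= burn && ((t - burn + 1) % storeInterval == 0)) {
            double msum = 0.0;
            for (int a = 0; a < N; ++a) {
                conf(stored, a) = (int) sigma[a];
                msum += sigma[a];
            }
            M[stored] = msum / N;
            ++stored;
            if (stored == nSamples) break;
        }
    }

    return List::create(_["configurations"] = conf, _["M"] = M,
                        _["fieldCheckError"] = maxFieldErr);
}
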
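#include <Rcpp.h>
using namespace Rcpp;

// Empirical pairwise heavy-atom energy, kcal/mol:
//   repulsion   k_rep * (r_i + r_j - d)^2          when d < r_i + r_j
//   C-C contact -eps_contact * ramp(d) linear 1->0 over [r_sum, cutoff]
//   h-bond      -eps_hbond * ramp(d)   linear 1->0 over [hb_lo, hb_hi],
//               both atoms N or O
//   Coulomb     scale * q_i q_j / (slope * d * d), d floored at 2 A,
//               charged-group representative atoms only
struct EnergyPar {
  double k_rep, eps_contact, contact_cutoff, eps_hbond, hb_lo, hb_hi;
  double coulomb_scale, dielectric_slope;
};

static inline double pair_energy(double d, double ri, double rj,
                                 int ci, int cj, int noi, int noj,
                                 double qi, double qj,
                                 const EnergyPar &p) {
  double e = 0.0;
  double rsum = ri + rj;
  if (d < rsum) {
    double x = rsum - d;
    e += p.k_rep * x * x;
  }
  if (ci && cj && d >= rsum && d <= p.contact_cutoff && p.contact_cutoff > rsum)
    e += -p.eps_contact * (p.contact_cutoff - d) / (p.contact_cutoff - rsum);
  if (noi && noj && d >= p.hb_lo && d <= p.hb_hi)
    e += -p.eps_hbond * (p.hb_hi - d) / (p.hb_hi - p.hb_lo);
  if (qi != 0.0 && qj != 0.0) {
    double dd = d < 2.0 ? 2.0 : d;
    e += p.coulomb_scale * qi * qj / (p.dielectric_slope * dd * dd);
  }
  return e;
}

static EnergyPar make_par(List par) {
  EnergyPar p;
  p.k_rep = as<double>(par["k_rep"]);
  p.eps_contact = as<double>(par["eps_contact"]);
  p.contact_cutoff = as<double>(par["contact_cutoff"]);
  p.eps_hbond = as<double>(par["eps_hbond"]);
  NumericVector w = par["hbond_window"];
  p.hb_lo = w[0]; p.hb_hi = w[1];
  p.coulomb_scale = as<double>(par["coulomb_scale"]);
  p.dielectric_slope = as<double>(par["dielectric_slope"]);
  return p;
}

// Sum over unordered atom pairs with >=1 atom selected (or all pairs when
// neighbourhood_only is false). Exclusions: same residue; backbone-backbone
// of sequence-adjacent residues in the same chain.
// [[Rcpp::export]]
double cpp_score_pairs(NumericMatrix xyz, NumericVector radius,
                       IntegerVector isC, IntegerVector isNO,
                       NumericVector charge, IntegerVector rid,
                       IntegerVector chain_id, IntegerVector seq_pos,
                       IntegerVector is_bb, IntegerVector sel,
                       bool neighbourhood_only, List par) {
  EnergyPar p = make_par(par);
  int n = xyz.nrow();
  double total = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (neighbourhood_only && !sel[i] && !sel[j]) continue;
      if (rid[i] == rid[j]) continue;
      if (is_bb[i] && is_bb[j] && chain_id[i] == chain_id[j] &&
          abs(seq_pos[i] - seq_pos[j]) == 1) continue;
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      double d = sqrt(dx * dx + dy * dy + dz * dz);
      total += pair_energy(d, radius[i], radius[j], isC[i], isC[j],
                           isNO[i], isNO[j], charge[i], charge[j], p);
    }
  }
  return total;
}

// Interaction energy of each candidate sidechain (rows of cand_xyz grouped
// in blocks of n_atoms) against a fixed environment. Same-residue pairs are
// excluded by construction (the environment never contains the residue).
// [[Rcpp::export]]
NumericVector cpp_candidate_energies(NumericMatrix cand_xyz, int n_atoms,
                                     NumericVector cradius,
                                     IntegerVector cisC, IntegerVector cisNO,
                                     NumericVector ccharge,
                                     NumericMatrix env_xyz,
                                     NumericVector eradius,
                                     IntegerVector eisC, IntegerVector eisNO,
                                     NumericVector echarge, List par) {
  EnergyPar p = make_par(par);
  int ncand = n_atoms > 0 ? cand_xyz.nrow() / n_atoms : 0;
  int ne = env_xyz.nrow();
  NumericVector out(ncand);
  for (int g = 0; g < ncand; ++g) {
    double e = 0.0;
    for (int a = 0; a < n_atoms; ++a) {
      int i = g * n_atoms + a;
      double xi = cand_xyz(i, 0), yi = cand_xyz(i, 1), zi = cand_xyz(i, 2);
      for (int j = 0; j < ne; ++j) {
        double dx = xi - env_xyz(j, 0);
        double dy = yi - env_xyz(j, 1);
        double dz = zi - env_xyz(j, 2);
        double d = sqrt(dx * dx + dy * dy + dz * dz);
        e += pair_energy(d, cradius[a], eradius[j], cisC[a], eisC[j],
                         cisNO[a], eisNO[j], ccharge[a], echarge[j], p);
      }
    }
    out[g] = e;
  }
  return out;
}
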
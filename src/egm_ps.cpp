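// Electrogram transfer-matrix assembly and phase-winding evaluation.
//
// The unipolar extracellular potential at a point electrode is the volume
// integral over the myocardium of -sigma_e * grad(Vm) . grad(1/r).  With
// linear elements grad(Vm) is constant per element, so the potential is a
// fixed linear map of the nodal Vm vector: phi = T %*% vm.  T depends only
// on geometry, conductivity and quadrature, and is assembled here once.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct QuadRule {
  std::vector<double> b1, b2, b3, w;  // barycentric coords and weights
};

static QuadRule quad_rule(int order) {
  QuadRule q;
  if (order <= 1) {                       // degree 1, centroid
    q.b1 = {1.0 / 3}; q.b2 = {1.0 / 3}; q.b3 = {1.0 / 3}; q.w = {1.0};
  } else if (order <= 2) {                // degree 2, 3 points
    q.b1 = {2.0 / 3, 1.0 / 6, 1.0 / 6};
    q.b2 = {1.0 / 6, 2.0 / 3, 1.0 / 6};
    q.b3 = {1.0 / 6, 1.0 / 6, 2.0 / 3};
    q.w = {1.0 / 3, 1.0 / 3, 1.0 / 3};
  } else {                                // degree 6, 12-point Dunavant rule
    const double w1 = 0.050844906370207, a1 = 0.873821971016996,
                 b1 = 0.063089014491502;
    const double w2 = 0.116786275726379, a2 = 0.501426509658179,
                 b2 = 0.249286745170910;
    const double w3 = 0.082851075618374, a3 = 0.636502499121399,
                 b3 = 0.310352451033785, c3 = 0.053145049844816;
    double B1[12] = {a1, b1, b1, a2, b2, b2, a3, a3, b3, b3, c3, c3};
    double B2[12] = {b1, a1, b1, b2, a2, b2, b3, c3, a3, c3, a3, b3};
    double B3[12] = {b1, b1, a1, b2, b2, a2, c3, b3, c3, a3, b3, a3};
    double W[12] = {w1, w1, w1, w2, w2, w2, w3, w3, w3, w3, w3, w3};
    q.b1.assign(B1, B1 + 12); q.b2.assign(B2, B2 + 12);
    q.b3.assign(B3, B3 + 12); q.w.assign(W, W + 12);
  }
  return q;
}

// nodes: n x 3 (cm); elements: m x 3 one-based; electrodes: ne x 3 (cm).
// Returns the ne x n transfer matrix T such that phi_e = T vm  (vm in mV).
// sigma_e in mS/cm, thickness in cm.  Throws if an electrode coincides
// with a quadrature point.
// [[Rcpp::export]]
NumericMatrix egm_transfer_cpp(NumericMatrix nodes, IntegerMatrix elements,
                               NumericMatrix electrodes, double sigma_e,
                               double thickness, int quad_order,
                               CharacterVector elec_labels) {
  const int m = elements.nrow(), ne = electrodes.nrow(), n = nodes.nrow();
  QuadRule q = quad_rule(quad_order);
  const int nq = q.w.size();
  NumericMatrix T(ne, n);

  for (int el = 0; el < m; ++el) {
    const int i1 = elements(el, 0) - 1, i2 = elements(el, 1) - 1,
              i3 = elements(el, 2) - 1;
    double p1[3], p2[3], p3[3], u[3], v[3], nrm[3];
    for (int d = 0; d < 3; ++d) {
      p1[d] = nodes(i1, d); p2[d] = nodes(i2, d); p3[d] = nodes(i3, d);
      u[d] = p2[d] - p1[d]; v[d] = p3[d] - p1[d];
    }
    nrm[0] = u[1] * v[2] - u[2] * v[1];
    nrm[1] = u[2] * v[0] - u[0] * v[2];
    nrm[2] = u[0] * v[1] - u[1] * v[0];
    const double two_area = std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1] +
                                      nrm[2] * nrm[2]);
    if (two_area <= 0) continue;
    const double area = 0.5 * two_area;
    for (int d = 0; d < 3; ++d) nrm[d] /= two_area;  // unit normal

    // gradients of the linear shape functions: grad(phi_i) = n x e_i / 2A,
    // with e_i the edge opposite vertex i, oriented CCW
    double g[3][3];
    double e1[3], e2[3], e3[3];
    for (int d = 0; d < 3; ++d) {
      e1[d] = p3[d] - p2[d];  // opposite vertex 1
      e2[d] = p1[d] - p3[d];
      e3[d] = p2[d] - p1[d];
    }
    auto cross_into = [&](const double *a, double *out) {
      out[0] = nrm[1] * a[2] - nrm[2] * a[1];
      out[1] = nrm[2] * a[0] - nrm[0] * a[2];
      out[2] = nrm[0] * a[1] - nrm[1] * a[0];
    };
    cross_into(e1, g[0]); cross_into(e2, g[1]); cross_into(e3, g[2]);
    for (int k = 0; k < 3; ++k)
      for (int d = 0; d < 3; ++d) g[k][d] /= two_area;

    const double vol_w = thickness * area;  // volume weight of the element
    for (int e = 0; e < ne; ++e) {
      double acc[3] = {0.0, 0.0, 0.0};  // integral of grad_source(1/r)... sign below
      for (int iq = 0; iq < nq; ++iq) {
        double xq[3], rvec[3];
        double r2 = 0.0;
        for (int d = 0; d < 3; ++d) {
          xq[d] = q.b1[iq] * p1[d] + q.b2[iq] * p2[d] + q.b3[iq] * p3[d];
          rvec[d] = xq[d] - electrodes(e, d);
          r2 += rvec[d] * rvec[d];
        }
        if (r2 < 1e-20)
          stop("electrode '%s' coincides with a quadrature point",
               std::string(elec_labels[e]).c_str());
        const double inv_r3 = 1.0 / (r2 * std::sqrt(r2));
        for (int d = 0; d < 3; ++d) acc[d] += q.w[iq] * rvec[d] * inv_r3;
      }
      // phi += -sigma_e * gradVm . grad(1/r) dV; grad(1/r) = -(x - x')/r^3
      // => contribution = +sigma_e * gradVm . (x - x')/r^3 dV
      for (int k = 0; k < 3; ++k) {
        const double c = sigma_e * vol_w *
          (g[k][0] * acc[0] + g[k][1] * acc[1] + g[k][2] * acc[2]);
        const int node = (k == 0) ? i1 : (k == 1 ? i2 : i3);
        T(e, node) += c;
      }
    }
  }
  return T;
}

// ---------------------------------------------------------------------------
// Phase winding around ordered one-rings
// ---------------------------------------------------------------------------

static inline double wrap_pi(double x) {
  // wrap to (-pi, pi] (floor-based; inputs are O(pi) so no precision issue)
  const double twopi = 2.0 * M_PI;
  x -= twopi * std::floor((x + M_PI) / twopi);  // now in [-pi, pi)
  if (x <= -M_PI) x += twopi;                   // convention: (-pi, pi]
  return x;
}

// phase: n x nt matrix (radians, NA allowed); rings in CSR form
// (ring_offsets length n+1, ring_nodes one-based, each ring an ordered
// closed cycle, counterclockwise about the outward normal).  frames:
// one-based column indices to evaluate.  Returns a list (one per frame)
// of integer matrices with columns (node, charge).
// [[Rcpp::export]]
List ps_detect_cpp(NumericMatrix phase, IntegerVector ring_offsets,
                   IntegerVector ring_nodes, IntegerVector frames) {
  const int n = phase.nrow();
  List out(frames.size());
  for (int f = 0; f < frames.size(); ++f) {
    const int col = frames[f] - 1;
    std::vector<int> ps_node, ps_charge;
    for (int i = 0; i < n; ++i) {
      const int a = ring_offsets[i], b = ring_offsets[i + 1];
      const int len = b - a;
      if (len < 3) continue;  // no closed ring (boundary / non-manifold)
      double winding = 0.0;
      bool ok = true;
      for (int k = 0; k < len; ++k) {
        const int n1 = ring_nodes[a + k] - 1;
        const int n2 = ring_nodes[a + (k + 1) % len] - 1;
        const double t1 = phase(n1, col), t2 = phase(n2, col);
        if (ISNAN(t1) || ISNAN(t2)) { ok = false; break; }
        winding += wrap_pi(t2 - t1);
      }
      if (!ok) continue;
      if (std::fabs(winding) > M_PI) {
        ps_node.push_back(i + 1);
        ps_charge.push_back(winding > 0 ? 1 : -1);
      }
    }
    IntegerMatrix res(ps_node.size(), 2);
    for (size_t k = 0; k < ps_node.size(); ++k) {
      res(k, 0) = ps_node[k];
      res(k, 1) = ps_charge[k];
    }
    colnames(res) = CharacterVector::create("node", "charge");
    out[f] = res;
  }
  return out;
}
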
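"""RDKit chemistry backend for the equivs R package.

All commands read a JSON request from --in and write a JSON response to
--out.  The R side owns graph featurization, alignment and the model; this
script only performs chemistry perception: structure standardization, ETKDG
conformer embedding, MMFF94 optimization, and multi-conformer SDF I/O.

Protocol notes:
  * atom indices are 0-based and refer to the heavy-atom order of
    Chem.MolFromSmiles(smiles); AddHs appends hydrogens after the heavy
    atoms, so heavy-atom rows always come first in coordinate arrays.
  * per-molecule failures are reported as {"ok": false, "error": ...}
    entries, never as a process failure.
"""

import argparse
import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")

HYBRIDIZATIONS = ("S", "SP", "SP2", "SP3", "SP3D", "SP3D2")


def _atom_record(atom):
    return {
        "symbol": atom.GetSymbol(),
        "degree": atom.GetDegree(),
        "implicit_h": atom.GetNumImplicitHs(),
        "formal_charge": atom.GetFormalCharge(),
        "radical_electrons": atom.GetNumRadicalElectrons(),
        "hybridization": str(atom.GetHybridization()),
        "aromatic": bool(atom.GetIsAromatic()),
        "total_h": atom.GetTotalNumHs(),
    }


def _bond_records(mol):
    # kekulized copy supplies integer orders for SDF output
    kek = Chem.Mol(mol)
    try:
        Chem.Kekulize(kek, clearAromaticFlags=True)
    except Exception:
        kek = mol
    out = []
    for bond in mol.GetBonds():
        kbond = kek.GetBondBetweenAtoms(bond.GetBeginAtomIdx(),
                                        bond.GetEndAtomIdx())
        korder = int(kbond.GetBondTypeAsDouble()) if kbond else 1
        out.append({
            "begin": bond.GetBeginAtomIdx(),
            "end": bond.GetEndAtomIdx(),
            "bond_type": str(bond.GetBondType()),
            "kekulized_order": korder,
            "conjugated": bool(bond.GetIsConjugated()),
            "in_ring": bool(bond.IsInRing()),
            "stereo": str(bond.GetStereo()),
        })
    return out


def _perception(mol):
    """Topology + atom/bond perception of a heavy-atom molecule."""
    return {
        "n_heavy": mol.GetNumAtoms(),
        "n_rings": mol.GetRingInfo().NumRings(),
        "atoms": [_atom_record(a) for a in mol.GetAtoms()],
        "bonds": _bond_records(mol),
        "smiles_canonical": Chem.MolToSmiles(mol),
    }


def cmd_standardize(req):
    results = []
    uncharger = rdMolStandardize.Uncharger()
    te = None
    for entry in req["molecules"]:
        smi = entry["smiles"]
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            results.append({"id": entry["id"], "ok": False,
                            "error": "parse_error",
                            "message": "unparseable SMILES: %r" % smi})
            continue
        flags = []
        try:
            before = Chem.MolToSmiles(mol)
            mol = rdMolStandardize.Cleanup(mol)
            if Chem.MolToSmiles(mol) != before:
                flags.append("cleanup")
            n_frags = len(Chem.GetMolFrags(mol))
            mol = rdMolStandardize.FragmentParent(mol)
            if n_frags > 1:
                flags.append("fragment_parent")
            if mol is None or mol.GetNumAtoms() == 0:
                results.append({"id": entry["id"], "ok": False,
                                "error": "empty_molecule",
                                "message": "no parent fragment left"})
                continue
            before = Chem.MolToSmiles(mol)
            mol = uncharger.uncharge(mol)
            if Chem.MolToSmiles(mol) != before:
                flags.append("uncharge")
            if req.get("canonical_tautomer", True):
                if te is None:
                    te = rdMolStandardize.TautomerEnumerator()
                before = Chem.MolToSmiles(mol)
                mol = te.Canonicalize(mol)
                if Chem.MolToSmiles(mol) != before:
                    flags.append("tautomer_canonical")
            smi_can = Chem.MolToSmiles(mol)
            check = Chem.MolFromSmiles(smi_can)
            if check is None:
                raise ValueError("canonical SMILES failed to re-parse")
            results.append({"id": entry["id"], "ok": True,
                            "smiles_canonical": smi_can,
                            "n_heavy_atoms": check.GetNumAtoms(),
                            "n_rings": check.GetRingInfo().NumRings(),
                            "flags": flags})
        except Exception as exc:  # standardization failure -> rejected
            results.append({"id": entry["id"], "ok": False,
                            "error": "standardization_error",
                            "message": str(exc)})
    return {"results": results}


def _etkdg(seed):
    ps = AllChem.ETKDG()
    ps.randomSeed = int(seed)
    return ps


def _embed_one(smiles, n_conformers, seed, max_retries=5):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None, "parse_error", "unparseable SMILES: %r" % smiles
    molh = Chem.AddHs(mol)
    coords = []
    conf_seeds = []
    for m in range(n_conformers):
        cid = -1
        used = None
        # deterministic retry ladder: seed+m, then incremented seeds,
        # then one random-coordinate fallback
        for attempt in range(max_retries + 1):
            trial = Chem.Mol(molh)
            ps = _etkdg(seed + m + attempt * 7919)
            cid = AllChem.EmbedMolecule(trial, ps)
            if cid >= 0:
                used = trial
                break
        if cid < 0:
            trial = Chem.Mol(molh)
            ps = _etkdg(seed + m)
            ps.useRandomCoords = True
            cid = AllChem.EmbedMolecule(trial, ps)
            if cid >= 0:
                used = trial
        if cid < 0:
            return None, "embedding_error", \
                "conformer %d failed to embed for %r" % (m, smiles)
        conf = used.GetConformer(cid)
        coords.append([[conf.GetAtomPosition(i).x,
                        conf.GetAtomPosition(i).y,
                        conf.GetAtomPosition(i).z]
                       for i in range(used.GetNumAtoms())])
        conf_seeds.append(seed + m)
    rec = _perception(mol)
    rec.update({
        "elements": [a.GetSymbol() for a in molh.GetAtoms()],
        "n_atoms": molh.GetNumAtoms(),
        "coords": coords,
        "conf_seeds": conf_seeds,
    })
    rec["energies"] = _mmff_energies(molh, coords)
    return rec, None, None


def _mol_with_coords(smiles, coords, with_h):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None
    if with_h:
        mol = Chem.AddHs(mol)
    if mol.GetNumAtoms() != len(coords[0]):
        return None
    mol.RemoveAllConformers()
    for xyz in coords:
        conf = Chem.Conformer(mol.GetNumAtoms())
        for i, (x, y, z) in enumerate(xyz):
            conf.SetAtomPosition(i, (float(x), float(y), float(z)))
        mol.AddConformer(conf, assignId=True)
    return mol


def _mmff_energies(molh, coords):
    mol = Chem.Mol(molh)
    mol.RemoveAllConformers()
    for xyz in coords:
        conf = Chem.Conformer(mol.GetNumAtoms())
        for i, (x, y, z) in enumerate(xyz):
            conf.SetAtomPosition(i, (float(x), float(y), float(z)))
        mol.AddConformer(conf, assignId=True)
    props = AllChem.MMFFGetMoleculeProperties(mol)
    if props is None:
        return None
    energies = []
    for cid in range(mol.GetNumConformers()):
        ff = AllChem.MMFFGetMoleculeForceField(mol, props, confId=cid)
        energies.append(ff.CalcEnergy() if ff is not None else None)
    return energies


def cmd_embed(req):
    n_conf = int(req.get("n_conformers", 10))
    seed = int(req.get("seed", 0))
    results = []
    for entry in req["molecules"]:
        rec, err, msg = _embed_one(entry["smiles"], n_conf, seed)
        if rec is None:
            results.append({"id": entry["id"], "ok": False,
                            "error": err, "message": msg})
        else:
            rec.update({"id": entry["id"], "ok": True, "seed": seed})
            results.append(rec)
    return {"results": results}


def cmd_optimize(req):
    max_iters = int(req.get("max_iters", 200))
    results = []
    for entry in req["molecules"]:
        mol = _mol_with_coords(entry["smiles"], entry["coords"], with_h=True)
        if mol is None:
            results.append({"id": entry["id"], "ok": False,
                            "error": "consistency_error",
                            "message": "SMILES/coordinate mismatch"})
            continue
        props = AllChem.MMFFGetMoleculeProperties(mol)
        if props is None:
            results.append({"id": entry["id"], "ok": False,
                            "error": "forcefield_error",
                            "message": "MMFF94 has no parameters for %r"
                                       % entry["smiles"]})
            continue
        coords, energies, converged = [], [], []
        for cid in range(mol.GetNumConformers()):
            ff = AllChem.MMFFGetMoleculeForceField(mol, props, confId=cid)
            if max_iters > 0:
                status = ff.Minimize(maxIts=max_iters)
            else:
                status = 1  # not run
            energies.append(ff.CalcEnergy())
            converged.append(status == 0)
            conf = mol.GetConformer(cid)
            coords.append([[conf.GetAtomPosition(i).x,
                            conf.GetAtomPosition(i).y,
                            conf.GetAtomPosition(i).z]
                           for i in range(mol.GetNumAtoms())])
        results.append({"id": entry["id"], "ok": True, "coords": coords,
                        "energies": energies, "converged": converged})
    return {"results": results}


def cmd_sdf_write(req):
    writer = Chem.SDWriter(req["path"])
    writer.SetKekulize(True)
    n_written = 0
    results = []
    for entry in req["molecules"]:
        mol = _mol_with_coords(entry["smiles"], entry["coords"],
                               with_h=bool(entry.get("with_h", False)))
        if mol is None:
            results.append({"id": entry["id"], "ok": False,
                            "error": "consistency_error",
                            "message": "SMILES/coordinate mismatch"})
            continue
        for cid in range(mol.GetNumConformers()):
            mol.SetProp("_Name", str(entry["id"]))
            mol.SetProp("conformer_index", str(cid + 1))
            if entry.get("label") is not None:
                mol.SetProp("value_logM", str(entry["label"]))
            writer.write(mol, confId=cid)
            n_written += 1
        results.append({"id": entry["id"], "ok": True,
                        "n_conformers": mol.GetNumConformers()})
    writer.close()
    return {"results": results, "n_records": n_written}


def cmd_sdf_read(req):
    try:
        supplier = Chem.SDMolSupplier(req["path"], removeHs=True)
    except OSError as exc:
        return {"results": [], "n_records": 0,
                "error": "format_error", "message": str(exc)}
    groups = {}   # id -> {"mol": first heavy mol, "coords": [...], ...}
    order = []
    n_records = 0
    for mol in supplier:
        if mol is None:
            continue
        n_records += 1
        name = mol.GetProp("_Name") if mol.HasProp("_Name") else ""
        if name == "":
            name = "mol%05d" % (len(order) + 1)
        conf = mol.GetConformer()
        xyz = [[conf.GetAtomPosition(i).x, conf.GetAtomPosition(i).y,
                conf.GetAtomPosition(i).z] for i in range(mol.GetNumAtoms())]
        label = float(mol.GetProp("value_logM")) \
            if mol.HasProp("value_logM") else None
        if name not in groups:
            groups[name] = {"mol": mol, "coords": [], "label": label}
            order.append(name)
        groups[name]["coords"].append(xyz)
    if n_records == 0:
        return {"results": [], "n_records": 0,
                "error": "format_error",
                "message": "no valid SDF records in %r" % req["path"]}
    results = []
    for name in order:
        grp = groups[name]
        mol = grp["mol"]
        rec = _perception(mol)
        rec.update({
            "id": name, "ok": True,
            "elements": [a.GetSymbol() for a in mol.GetAtoms()],
            "n_atoms": mol.GetNumAtoms(),
            "coords": grp["coords"],
            "label": grp["label"],
        })
        results.append(rec)
    return {"results": results, "n_records": n_records}


COMMANDS = {
    "standardize": cmd_standardize,
    "embed": cmd_embed,
    "optimize": cmd_optimize,
    "sdf_write": cmd_sdf_write,
    "sdf_read": cmd_sdf_read,
}


def main(argv=None):
    ap = argparse.ArgumentParser(description=__doc__)
    ap.add_argument("command", choices=sorted(COMMANDS))
    ap.add_argument("--in", dest="infile", required=True)
    ap.add_argument("--out", dest="outfile", required=True)
    args = ap.parse_args(argv)
    with open(args.infile) as fh:
        req = json.load(fh)
    res = COMMANDS[args.command](req)
    with open(args.outfile, "w") as fh:
        json.dump(res, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main())
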
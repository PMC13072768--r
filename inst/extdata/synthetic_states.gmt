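programmed_cell_death	synthetic	g00347	g01005	g00025	g01774	g00063	g00487	g01505	g01735	g00044	g01622	g01076	g00435	g00708	g00300	g01430	g00748	g01390	g01799	g00293	g00459
senescence	synthetic	g01006	g01527	g00615	g01698	g00199	g00413	g01619	g00517	g00381	g01222	g01966	g01604	g01469	g01805	g00897	g00630	g01894	g00746	g00919	g01945
cell_cycle_arrest	synthetic	g01702	g01061	g01627	g01093	g00323	g01617	g00023	g01861	g00640	g01968	g01316	g00350	g00276	g00177	g01970	g01649	g01367	g00131	g00084	g01296
drug_resistance	synthetic	g01932	g00818	g01337	g00777	g01976	g01579	g01444	g00174	g01229	g01007	g01811	g01732	g01546	g00530	g00657	g01728	g01526	g00090	g00598	g00766
immune_escape	synthetic	g01597	g01412	g01984	g00812	g01841	g00947	g01079	g00680	g01329	g00511	g01210	g00241	g01906	g01832	g00196	g01882	g00056	g01058	g00162	g01788
malignant_progression	synthetic	g01943	g00398	g00377	g01419	g01230	g01900	g00844	g01990	g01231	g00845	g01104	g00863	g00249	g01502	g01842	g00390	g00406	g01656	g00152	g00296
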
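# Grid carbon intensity of electricity generation, g CO2e per kWh.
# Approximate country-level values for the 2023 vintage; intended as
# editable defaults only. Users should refresh this file from a current
# public dataset of electricity carbon intensity for their country before
# relying on the band assignment near the 100 / 300 g boundaries.
country,g_co2e_per_kwh,year,source_note
Sweden,41,2023,approximate 2023 grid intensity
Norway,30,2023,approximate 2023 grid intensity
Iceland,28,2023,approximate 2023 grid intensity
France,56,2023,approximate 2023 grid intensity
Brazil,96,2023,approximate 2023 grid intensity
Canada,171,2023,approximate 2023 grid intensity
Spain,174,2023,approximate 2023 grid intensity
United Kingdom,238,2023,approximate 2023 grid intensity
Italy,331,2023,approximate 2023 grid intensity
United States,369,2023,approximate 2023 grid intensity
Germany,381,2023,approximate 2023 grid intensity
Egypt,469,2023,approximate 2023 grid intensity
Japan,485,2023,approximate 2023 grid intensity
Australia,549,2023,approximate 2023 grid intensity
China,582,2023,approximate 2023 grid intensity
Poland,661,2023,approximate 2023 grid intensity
South Africa,708,2023,approximate 2023 grid intensity
India,713,2023,approximate 2023 grid intensity
Libya,819,2023,approximate 2023 grid intensity
Kazakhstan,821,2023,approximate 2023 grid intensity
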